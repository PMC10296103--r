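# Small in-code fixtures shared across test files.

# item table for three hand-scored participants
toy_items <- function() {
  base <- data.frame(id = c("A", "B", "C"),
                     group = c("cis_boy", "gd_afab", "cis_girl"),
                     age_months = c(150L, 180L, 210L),
                     stringsAsFactors = FALSE)
  andro <- rbind(rep(5L, 8), c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L), rep(3L, 8))
  gyne  <- rbind(rep(1L, 8), rep(2L, 8), rep(3L, 8))
  gid   <- rbind(matrix(5L, 1, 27), matrix(2L, 1, 27), matrix(5L, 1, 27))
  colnames(andro) <- paste0("eros_andro_", 1:8)
  colnames(gyne)  <- paste0("eros_gyne_", 1:8)
  colnames(gid)   <- paste0("gidyq_", 1:27)
  cbind(base, andro, gyne, gid)
}

# two-ROI cube volume set with constant metric values
toy_volumes <- function(metric_vals = c(1000, 2000), gm = 0.9) {
  dims <- c(8L, 4L, 4L)
  lab <- array(0L, dims); met <- array(0, dims); gmp <- array(0, dims)
  lab[1:4, , ] <- 1L; lab[5:8, , ] <- 2L
  met[1:4, , ] <- metric_vals[1]; met[5:8, , ] <- metric_vals[2]
  gmp[] <- gm
  volume_set(met, gmp, lab)
}

# brain/behavior data with one latent dimension planted in groups 1-2
planted_pls_data <- function(n_per_group = 50L, n_cols = 60L,
                             planted = 1:10, effect = 0.6, seed = 1L) {
  set.seed(seed)
  n <- 3L * n_per_group
  groups <- rep(c("g1", "g2", "g3"), each = n_per_group)
  y <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("strength", "degree", "age")))
  eta <- rowMeans(y) * sqrt(3)
  aff <- as.numeric(groups != "g3")
  x <- matrix(rnorm(n * n_cols), n, n_cols)
  x[, planted] <- x[, planted] + effect * (eta * aff)
  list(x = x, y = y, groups = groups, planted = planted)
}
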