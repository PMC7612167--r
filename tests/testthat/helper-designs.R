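# Published design realisations used across tests.  Block-design thresholds
# are printed rounded to 4 (or 3) decimals and are snapped onto the
# attainable conditional-power grid when the design is built.

# (alpha, beta, p0, p1) = (0.15, 0.20, 0.30, 0.50)
published_block_rows_main <- function() {
  rows <- list(
    list(label = "p0-optimal, block 2", r = 5, n = 116, block = 1,
         theta_f = 0.1348, theta_e = 0.9831, ess00 = 47.3, ess01 = 47.2),
    list(label = "p0-optimal, block 8", r = 5, n = 112, block = 4,
         theta_f = 0.3005, theta_e = 0.9700, ess00 = 49.2, ess01 = 49.3),
    list(label = "p1-optimal, block 2", r = 6, n = 112, block = 1,
         theta_f = 0.1072, theta_e = 0.9740, ess00 = 47.9, ess01 = 45.4),
    list(label = "minimax, block 2", r = 4, n = 80, block = 1,
         theta_f = 0.0428, theta_e = 0.9842, ess00 = 57.3, ess01 = 52.7),
    list(label = "minimax, block 8", r = 4, n = 80, block = 4,
         theta_f = 0.0609, theta_e = 0.9752, ess00 = 62.2, ess01 = 57.1))
  for (i in seq_along(rows)) { rows[[i]]$p0 <- 0.3; rows[[i]]$p1 <- 0.5 }
  rows
}

# (alpha, beta, p0, p1) = (0.15, 0.20, 0.70, 0.85)
published_block_rows_calgb <- function() {
  rows <- list(
    list(label = "p0/p1-optimal, block 2", r = 6, n = 198, block = 1,
         theta_f = 0.1108, theta_e = 0.9928, ess00 = 61.1, ess01 = 79.4),
    list(label = "p0-optimal, block 8", r = 4, n = 176, block = 4,
         theta_f = 0.3391, theta_e = 0.9965, ess00 = 64.4, ess01 = 87.7),
    list(label = "p1-optimal, block 8", r = 6, n = 184, block = 4,
         theta_f = 0.2730, theta_e = 0.9866, ess00 = 66.4, ess01 = 83.5),
    list(label = "minimax, block 2", r = 5, n = 124, block = 1,
         theta_f = 0.0064, theta_e = 0.9960, ess00 = 96.4, ess01 = 95.9),
    list(label = "minimax, block 8", r = 5, n = 128, block = 4,
         theta_f = 0.1304, theta_e = 0.9887, ess00 = 80.1, ess01 = 91.7))
  for (i in seq_along(rows)) { rows[[i]]$p0 <- 0.7; rows[[i]]$p1 <- 0.85 }
  rows
}

build_published <- function(row) {
  block_design(r = row$r, n = row$n, block = row$block,
               theta_f = row$theta_f, theta_e = row$theta_e,
               p0 = row$p0, p1 = row$p1, snap = TRUE)
}

# display convention of the published tables: one decimal, half-up
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
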