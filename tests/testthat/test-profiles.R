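# minimal hand-built sample bundle on a common window grid
toy_samples <- function(counts, timepoints, dna_content,
                        window_size = 500) {
  n <- nrow(counts)
  windows <- data.frame(chrom = "c", start = (0:(n - 1)) * window_size,
                        end = (1:n) * window_size)
  windows$mid <- (windows$start + windows$end) / 2
  n_s <- length(timepoints)
  other <- colnames(counts)[setdiff(seq_len(ncol(counts)), seq_len(n_s))]
  sheet <- data.frame(
    sample = colnames(counts),
    timepoint = c(timepoints, rep(NA, length(other))),
    role = c(rep("S", n_s), other),
    dna_content = c(dna_content, rep(NA, length(other))))
  sheet$dna_content[sheet$role == "G1"] <- 1
  list(windows = windows, counts = counts, sheet = sheet)
}

test_that("Trep is the linearly interpolated time of the 1.5 crossing", {
  # many identical windows so the median adjustment is the identity
  tr_vals <- rbind(c(1.0, 1.4, 1.6, 2.0))
  counts <- cbind(t(matrix(rep(t(tr_vals), 40), nrow = 4)),
                  G1 = rep(1, 40))
  colnames(counts) <- c("t10", "t20", "t30", "t40", "G1")
  smp <- toy_samples(counts, c(10, 20, 30, 40), c(1.0, 1.4, 1.6, 2.0))
  tr <- compute_trep(smp, "G1", span_bp = NULL)
  # trajectory (20, 1.4) -> (30, 1.6) crosses 1.5 at t = 25
  expect_equal(unique(round(tr$profile$value, 9)), 25)
})

test_that("a fully replicated window is flagged early-saturated at the first timepoint", {
  counts <- cbind(matrix(2, nrow = 30, ncol = 3), G1 = rep(1, 30))
  colnames(counts) <- c("t10", "t20", "t30", "G1")
  smp <- toy_samples(counts, c(10, 20, 30), c(2, 2, 2))
  tr <- compute_trep(smp, "G1", span_bp = NULL)
  expect_true(all(tr$profile$flag == "early_saturated"))
  expect_true(all(tr$profile$value == 10))
})

test_that("zero reference windows are dropped and G2 references are halved", {
  counts <- cbind(t10 = c(1, 1, 1, 1), t20 = c(1.5, 1.5, 1.5, 1.5),
                  t30 = c(2, 2, 2, 2), G2 = c(2, 2, 0, 2))
  counts <- counts[rep(1:4, each = 10), ]
  smp <- toy_samples(counts, c(10, 20, 30), c(1, 1.5, 2))
  tr <- compute_trep(smp, reference_role = "G2", span_bp = NULL)
  expect_equal(nrow(tr$profile), 30)  # ten dropped
  expect_equal(unique(round(tr$profile$value, 9)), 20)
})

test_that("noiseless synthetic Trep matches the analytic crossing within a timepoint spacing", {
  m <- fixture_model()
  des <- fixture_design(noise = "none")
  smp <- sample_sequencing(m, des, seed = 1)
  tr <- compute_trep(smp, "G1", span_bp = NULL)
  truth <- analytic_trep(m, "chrA", tr$profile$mid)
  err <- abs(tr$profile$value - truth)
  expect_lte(max(err, na.rm = TRUE), diff(des$timepoints)[1])
})

test_that("the adjusted ratio surface reproduces its centring statistic", {
  m <- fixture_model()
  smp <- sample_sequencing(m, fixture_design(), seed = 2)
  tr <- compute_trep(smp, "G1", span_bp = NULL, center = "median")
  rs <- tr$ratio_surface
  for (j in seq_along(rs$timepoints)) {
    expect_equal(stats::median(rs$ratio[, j]), rs$dna_content[j],
                 tolerance = 1e-9)
  }
})

test_that("MFA removes IQR outlier windows and identical tracks give ratio one", {
  base <- rep(100, 101)
  base[51] <- 1000  # single 10x outlier
  counts <- cbind(Expo = base, Stat = rep(100, 101))
  smp <- toy_samples(counts[, , drop = FALSE], numeric(0), numeric(0))
  smp$sheet <- data.frame(sample = c("Expo", "Stat"), timepoint = NA,
                          role = c("Expo", "Stat"), dna_content = NA)
  mfa <- compute_mfa(smp, span_bp = NULL)
  expect_equal(mfa$n_filtered, 1)
  expect_false(25250 %in% mfa$profile$mid)
  expect_true(all(mfa$profile$value == 1))
})

test_that("Trep and MFA are strongly rank-anticorrelated on noiseless data", {
  m <- fixture_model()
  smp <- sample_sequencing(m, fixture_design(noise = "none"), seed = 1)
  tr <- compute_trep(smp, "G1")
  mfa <- compute_mfa(smp)
  common <- merge(tr$profile[c("chrom", "start", "value")],
                  mfa$profile[c("chrom", "start", "value")],
                  by = c("chrom", "start"))
  rho <- stats::cor(common$value.x, common$value.y, method = "spearman",
                    use = "complete.obs")
  expect_lt(rho, -0.95)
})

test_that("smoothing stays within the observed value envelope and bridges gaps", {
  set.seed(5)
  n <- 400
  prof <- data.frame(chrom = "c", start = (0:(n - 1)) * 500,
                     end = (1:n) * 500)
  prof$mid <- prof$start + 250
  prof$value <- sin(prof$mid / 2e4) * 10 + 20 + rnorm(n, 0, 0.3)
  prof$value[150:160] <- NA
  sm <- smooth_profile(prof, span_bp = 20000)
  rng <- range(prof$value, na.rm = TRUE)
  eps <- 0.05 * diff(rng)
  expect_true(all(sm$value >= rng[1] - eps & sm$value <= rng[2] + eps,
                  na.rm = TRUE))
  expect_true(all(is.finite(sm$value[150:160])))  # gap bridged
})

test_that("normalization maps to [0,1] preserving order and rejects constants", {
  prof <- data.frame(chrom = "c", start = 0:2 * 500, end = 1:3 * 500,
                     mid = 0:2 * 500 + 250, value = c(10, 20, 30))
  nz <- normalize_timing(prof)
  expect_equal(nz$value, c(0, 0.5, 1))
  expect_equal(stats::cor(prof$value, nz$value, method = "spearman"), 1)
  prof$value <- 5
  expect_error(normalize_timing(prof), "constant")
})
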