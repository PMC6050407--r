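# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# O(B^2) brute-force Rao quadratic entropy over all ordered bin pairs
qe_brute_force <- function(centers, p) {
  sum(outer(p, p) * abs(outer(centers, centers, "-")))
}

# Sample from a log-normal mixture (receptors/cell scale) without going
# through the package's generator
rlnorm10_mix <- function(n, w, mu_log10, sigma_log10) {
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  10^rnorm(n, mu_log10[comp], sigma_log10[comp])
}

# Byte-level FCS 3.0 assembler, independent of write_fcs(): offsets are
# computed by hand and keywords are emitted in a different order/dialect.
assemble_fcs_bytes <- function(path, channels, mat) {
  stopifnot(is.matrix(mat), length(channels) == ncol(mat))
  n <- nrow(mat); p <- ncol(mat)
  d <- "|"
  kws <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
           "$NEXTDATA", "0",
           "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    kws <- c(kws, sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
             sprintf("$P%dN", i), channels[i], sprintf("$P%dR", i), "1048576")
  }
  make_text <- function(beg, end) {
    paste0(d, paste0(c(rbind(c(kws, "$BEGINDATA", sprintf("%09d", beg),
                               "$ENDDATA", sprintf("%09d", end)),
                             d)), collapse = ""))
  }
  text_start <- 58
  stub <- make_text(0, 0)
  data_start <- text_start + nchar(stub)
  data_end <- data_start + 4 * n * p - 1
  text <- make_text(data_start, data_end)
  stopifnot(nchar(text) == nchar(stub))
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + nchar(text) - 1,
                    data_start, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  # row-major event-interleaved values, little-endian float32
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  path
}

# Two-population truth for gating / composition tests
two_pop_truth <- function(frac_b = 0.1, noise_cv = 0) {
  mm_a <- list(VEGFR1 = data.frame(weight = 1, mu_log10 = 3.5,
                                   sigma_log10 = 0.2))
  mm_b <- list(VEGFR1 = data.frame(weight = 1, mu_log10 = 4.5,
                                   sigma_log10 = 0.2))
  neg <- setNames(rep("negative", length(GATING_CHANNELS)), GATING_CHANNELS)
  pos <- neg; pos["hCD34"] <- "positive"
  synthetic_truth(list(
    population_spec("A", 1 - frac_b, mm_a, neg),
    population_spec("B", frac_b, mm_b, pos)),
    slope = 1, intercept = 0, noise_cv = noise_cv)
}

# One-population, one-component truth
one_pop_truth <- function(mu = 3, sigma = 0.2, noise_cv = 0, slope = 1,
                          intercept = 0, rpf = 1) {
  mm <- list(VEGFR1 = data.frame(weight = 1, mu_log10 = mu,
                                 sigma_log10 = sigma))
  neg <- setNames(rep("negative", length(GATING_CHANNELS)), GATING_CHANNELS)
  synthetic_truth(list(population_spec("A", 1, mm, neg)),
                  slope = slope, intercept = intercept,
                  receptors_per_fluorophore = rpf, noise_cv = noise_cv)
}

# Minimal JSON pipeline config written to a temp file
write_minimal_config_json <- function(path, extra = list()) {
  cfg <- c(list(
    panel = list(PE = "VEGFR1"),
    gates = list(children = list(
      list(marker = "LiveDead", threshold = 1778, direction = "negative",
           label = "live")))),
    extra)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}
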