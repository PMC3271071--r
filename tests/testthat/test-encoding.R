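test_that("scheme dimensions reproduce the closed-form feature counts", {
  widths <- c("PB" = 20, "PB+PP" = 23, "PB+PP+SC" = 25,
              "PB+PP+DISO" = 25, "PB+PP+SC+DISO" = 27)
  for (scheme in names(widths)) {
    for (L in seq(3, 21, by = 2)) {
      expect_identical(scheme_dimension(scheme, L),
                       as.integer(widths[[scheme]] * L))
    }
  }
  expect_identical(scheme_dimension("PB", 3), 60L)
  expect_identical(scheme_dimension("PB+PP", 9), 207L)
  expect_identical(scheme_dimension("PB+PP+SC+DISO", 9), 243L)
  expect_identical(scheme_dimension("ALL", 9), 27L * 9L + 22L)
  expect_identical(scheme_dimension("ALL", 9, global_width = 34), 277L)
})

test_that("even or invalid windows and unknown schemes are errors", {
  expect_error(scheme_dimension("PB", 8), class = "phipsi_config_error")
  expect_error(scheme_dimension("PB+XX", 9), class = "phipsi_config_error")
})

test_that("global features compute composition, length and weight", {
  g <- compute_global_features("AAAA")
  expect_equal(g[["A"]], 1)
  expect_equal(sum(g[phipsi:::AA_ALPHABET]), 1)
  g2 <- compute_global_features("ACDE")
  expect_equal(unname(g2[c("A", "C", "D", "E")]), rep(0.25, 4))
  g3 <- compute_global_features("AXAX")
  expect_equal(g3[["A"]], 0.5)
  expect_equal(sum(g3[phipsi:::AA_ALPHABET]), 0.5)  # X excluded
  expect_equal(g3[["length"]], 4 / 1000)
  # weight: A + mean + A + mean residue masses, scaled by 1e-5
  mean_mass <- mean(phipsi:::AA_RESIDUE_MASS)
  expect_equal(g3[["weight"]], (2 * 71.0788 + 2 * mean_mass) / 1e5)
  long <- paste(rep("A", 1500), collapse = "")
  expect_equal(compute_global_features(long)[["length"]], 1)  # capped
})

test_that("window extraction is position-major with zero padding", {
  b <- make_toy_bundle("ACDEFGHIKL")
  # l = 1, scheme PB+PP: per-residue block = 20 pssm + 3 ss
  v <- encode_residue(b, 1, scheme = "PB+PP", l = 1)
  expect_length(v, scheme_dimension("PB+PP", 3))
  expect_equal(v[1:23], rep(0, 23))                       # left padding
  expect_equal(v[24:43], unname(b$pssm$normalized[1, ]))  # centre, PB block
  expect_equal(v[44:46], unname(b$ss$probs[1, ]))         # centre, PP block
  expect_equal(v[47:66], unname(b$pssm$normalized[2, ]))  # right neighbour

  # interior residue, full scheme: track order PB, PP, SC, DISO
  v2 <- encode_residue(b, 5, scheme = "PB+PP+SC+DISO", l = 1)
  centre <- v2[28:54]
  expect_equal(centre, unname(c(b$pssm$normalized[5, ], b$ss$probs[5, ],
                                b$sa$encoding[5, ], b$diso$encoding[5, ])))
})

test_that("every scheme produces vectors of the contracted width", {
  b <- make_toy_bundle("ACDEFGHIKLMNPQRSTVWY")
  for (scheme in encoding_schemes()) {
    for (l in c(1, 4)) {
      X <- encode_positions(b, c(1, 10, 20), scheme = scheme, l = l)
      expect_identical(ncol(X), scheme_dimension(scheme, 2 * l + 1))
      expect_identical(nrow(X), 3L)
    }
  }
})

test_that("the ALL scheme appends the global block once at the end", {
  b <- make_toy_bundle("ACDEFGHIKL")
  v <- encode_residue(b, 5, scheme = "ALL", l = 2)
  expect_length(v, scheme_dimension("ALL", 5))
  expect_equal(unname(tail(v, 22)), unname(b$global))
  base <- encode_residue(b, 5, scheme = "PB+PP+SC+DISO", l = 2)
  expect_equal(v[seq_along(base)], base)
})

test_that("encoding is translation-consistent under zero-track padding", {
  b <- make_toy_bundle("ACDEFGHIKL")
  k <- 3
  padded_seq <- paste0(strrep("A", k), b$seq)
  zero_rows <- function(m, k) rbind(matrix(0, k, ncol(m)), m)
  pss <- b$pssm; pss$raw <- zero_rows(pss$raw, k)
  pss$normalized <- zero_rows(pss$normalized, k)
  pss$letters <- c(rep("A", k), pss$letters)
  ssp <- b$ss; ssp$probs <- zero_rows(ssp$probs, k)
  ssp$state <- c(rep("C", k), ssp$state)
  sap <- b$sa; sap$encoding <- zero_rows(sap$encoding, k)
  sap$state <- c(rep("E", k), sap$state)   # state letters don't enter features
  sap$encoding[seq_len(k), ] <- 0
  dis <- b$diso
  dis$encoding <- zero_rows(dis$encoding, k)
  dis$p_disordered <- c(rep(0, k), dis$p_disordered)
  dis$p_ordered <- c(rep(0, k), dis$p_ordered)
  dis$encoding[seq_len(k), ] <- 0
  b2 <- profile_bundle("shifted", padded_seq, pss, ssp, sap, dis)
  for (i in c(1, 2, 5)) {
    expect_equal(
      encode_residue(b, i, scheme = "PB+PP+SC+DISO", l = 2),
      encode_residue(b2, i + k, scheme = "PB+PP+SC+DISO", l = 2))
  }
})

test_that("chain encoding keeps only residues with defined targets", {
  ds <- small_dataset(n_chains = 1)
  ch <- ds$chains[[1]]
  norm <- fit_angle_normalizer(ch$angles$phi, ch$angles$psi)
  enc <- encode_chain(ch$bundle, ch$angles, which = "phi", norm = norm,
                      scheme = "PB+PP", l = 4)
  n_def <- sum(!is.na(ch$angles$phi))
  expect_identical(nrow(enc$X), n_def)
  expect_identical(ncol(enc$X), scheme_dimension("PB+PP", 9))
  expect_identical(enc$index, which(!is.na(ch$angles$phi)))
  expect_equal(enc$y,
               normalize_angle(ch$angles$phi[enc$index], "phi", norm))

  # extra terminal trim removes rows from both ends
  enc2 <- encode_chain(ch$bundle, ch$angles, which = "phi", norm = norm,
                       scheme = "PB+PP", l = 4, extra_trim = 4)
  expect_identical(nrow(enc2$X), sum(!is.na(
    ch$angles$phi[5:(nrow(ch$angles) - 4)])))

  # all-undefined targets give an empty, validly shaped design
  blank <- ch$angles
  blank$phi <- NA_real_
  enc3 <- encode_chain(ch$bundle, blank, which = "phi", norm = norm,
                       scheme = "PB+PP", l = 4)
  expect_identical(nrow(enc3$X), 0L)
  expect_identical(ncol(enc3$X), scheme_dimension("PB+PP", 9))

  misaligned <- ch$angles[-1, ]
  expect_error(encode_chain(ch$bundle, misaligned, which = "phi",
                            norm = norm),
               class = "phipsi_consistency_error")
})

test_that("SVM-light sparse export round-trips", {
  set.seed(9)
  X <- matrix(rnorm(40), 5, 8)
  X[X < 0] <- 0
  y <- rnorm(5)
  path <- withr::local_tempfile(fileext = ".svml")
  write_svmlight(X, y, path)
  back <- read_svmlight(path, ncol = 8)
  expect_equal(back$X, X, tolerance = 1e-9)
  expect_equal(back$y, y, tolerance = 1e-9)
})
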