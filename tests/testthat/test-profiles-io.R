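write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("FASTA parsing folds lines, uppercases and maps unknowns to X", {
  fa <- write_lines_tmp(c(">a", "ACDE", ">b desc", "ac", "de"))
  out <- read_fasta(fa)
  expect_equal(out$id, c("a", "b"))
  expect_equal(out$seq, c("ACDE", "ACDE"))

  fa2 <- write_lines_tmp(c(">a", "ACZE"))
  expect_warning(out2 <- read_fasta(fa2), "mapped to X")
  expect_equal(out2$seq, "ACXE")

  empty <- write_lines_tmp(character(0))
  expect_error(read_fasta(empty), class = "phipsi_format_error")
})

make_pssm_lines <- function(scores) {
  # scores: n x 20 integer matrix
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("           ",
                     paste(phipsi:::PSSM_ALPHABET, collapse = "   ")))
  rows <- vapply(seq_len(nrow(scores)), function(i) {
    paste0(sprintf("%5d %s ", i, "A"),
           paste(sprintf("%3d", scores[i, ]), collapse = " "),
           "  ", paste(rep("0", 20), collapse = " "), " 0.36 0.09")
  }, character(1))
  c(header, rows)
}

test_that("PSSM scores are captured and scaled by exactly 1/10", {
  scores <- matrix(0L, 3, 20)
  scores[1, 1] <- 5L
  scores[2, 2] <- 0L
  scores[3, 3] <- -12L
  path <- write_lines_tmp(make_pssm_lines(scores))
  p <- read_pssm(path, seq_length = 3)
  expect_s3_class(p, "pssm_profile")
  expect_equal(unname(p$normalized[1, 1]), 0.5)
  expect_equal(unname(p$normalized[2, 2]), 0.0)
  expect_equal(unname(p$normalized[3, 3]), -1.2)  # no clamping outside [0, 1]
  expect_equal(p$normalized, p$raw / 10)
})

test_that("PSSM length and format inconsistencies are rejected", {
  path <- write_lines_tmp(make_pssm_lines(matrix(1L, 4, 20)))
  expect_error(read_pssm(path, seq_length = 5),
               class = "phipsi_consistency_error")
  bad <- make_pssm_lines(matrix(1L, 2, 20))
  bad[5] <- sub(" 1 ", " x ", bad[5], fixed = TRUE)
  expect_error(read_pssm(write_lines_tmp(bad)),
               class = "phipsi_format_error")
})

test_that("ss2 files parse with probabilities re-ordered to (H, E, C)", {
  path <- write_lines_tmp(c("# PSIPRED VFORMAT (PSIPRED V3.3)", "",
                            "  1 M C   0.900  0.050  0.050",
                            "  2 A H   0.100  0.800  0.100",
                            "  3 V E   0.200  0.100  0.700"))
  ss <- read_psipred_ss2(path)
  expect_equal(length(ss$state), 3)
  expect_equal(ss$state, c("C", "H", "E"))
  expect_equal(ss$probs[1, ], c(H = 0.05, E = 0.05, C = 0.9))
  expect_equal(ss$probs[3, ], c(H = 0.1, E = 0.7, C = 0.2))
})

test_that("malformed ss2 rows are format errors", {
  missing_state <- write_lines_tmp(c("  1 M 0.9 0.05 0.05"))
  expect_error(read_psipred_ss2(missing_state),
               class = "phipsi_format_error")
  bad_prob <- write_lines_tmp(c("  1 M C 1.9 0.05 0.05"))
  expect_error(read_psipred_ss2(bad_prob), class = "phipsi_format_error")
})

test_that("accessibility tracks accept folded strings and tables", {
  path <- write_lines_tmp("eebb")
  sa <- read_accessibility(path)
  expect_equal(sa$state, c("E", "E", "B", "B"))
  expect_equal(unname(sa$encoding),
               cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  tab <- write_lines_tmp(c("1 M e", "2 A b"))
  expect_equal(read_accessibility(tab)$state, c("E", "B"))
  expect_error(read_accessibility(write_lines_tmp("exb")),
               class = "phipsi_format_error")
  empty <- withr::local_tempfile(fileext = ".acc")
  file.create(empty)
  expect_error(read_accessibility(empty), class = "phipsi_format_error")
})

test_that("disorder probabilities parse with complements", {
  path <- write_lines_tmp(c("# mock", "  1 M * 0.73", "  2 A . 0.10"))
  d <- read_disorder(path)
  expect_equal(d$p_disordered, c(0.73, 0.10))
  expect_equal(d$p_ordered, c(0.27, 0.90))
  expect_error(read_disorder(write_lines_tmp("1 M * oops")),
               class = "phipsi_format_error")
})

test_that("angle tables round-trip and validate their shape", {
  rows <- tibble::tibble(
    resname = c("ALA", "GLY", "PRO"), chain = "A",
    pos = c("10", "11", "11A"),
    observed = c(-70.0, 65.1234, -75.5),
    normalized = c(0.5, 0.81, 0.47),
    ss = c("H", "C", "C"), sa = c("B", "E", "E"),
    disorder = c("O", "O", "D"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_angle_table(rows, path, angle = "phi")
  back <- read_angle_table(path, angle = "phi")
  expect_equal(attr(back, "angle"), "phi")
  attr(back, "angle") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(rows), tolerance = 1e-6)

  bad <- write_lines_tmp(c("ALA\tA\t1\t-70.0\t0.5\tH\tB\tO",
                           "GLY\tA\t2\t10\t0.5"))
  err <- tryCatch(read_angle_table(bad), error = identity)
  expect_s3_class(err, "phipsi_format_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("normalized column consistency is checkable against a normalizer", {
  norm <- fit_angle_normalizer(c(-60, -80), c(0, 100), span = 6)
  rows <- tibble::tibble(
    resname = "ALA", chain = "A", pos = "1",
    observed = -70, normalized = normalize_angle(-70, "phi", norm),
    ss = "H", sa = "B", disorder = "O")
  expect_equal(rows$normalized, 0.5)   # observed equals the pool mean
  expect_true(check_angle_table(rows, norm, "phi"))
  rows$normalized <- 0.9
  expect_error(check_angle_table(rows, norm, "phi"),
               class = "phipsi_consistency_error")
})

test_that("profile bundles reject length-inconsistent tracks", {
  b <- make_toy_bundle("ACDEFGHIKL")
  expect_s3_class(b, "profile_bundle")
  short_ss <- b$ss
  short_ss$probs <- short_ss$probs[1:5, ]
  expect_error(profile_bundle("x", b$seq, b$pssm, short_ss, b$sa, b$diso),
               class = "phipsi_consistency_error")
  td <- tidy(b)
  expect_equal(nrow(td), 10)
  expect_equal(td$aa[1:3], c("A", "C", "D"))
})
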