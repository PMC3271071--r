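## Synthetic chains with secondary-structure-conditioned torsion angles
## and correlated mock profile tracks, written in exactly the file
## dialects the readers accept, so the full train/predict/evaluate
## pipeline runs without any external predictor or download.
##
## The angle mixtures mimic the familiar Ramachandran clusters (one phi
## mode near -70 degrees; bimodal psi near -40 and +140; a tight proline
## phi near -75; a sign-symmetric glycine phi in coil).  They are design
## defaults of this generator, not fitted to any particular structure
## set.

#' Synthetic dataset configuration
#'
#' @param n_chains number of chains.
#' @param length_range min/max chain length (residues).
#' @param seg_length named mean segment lengths for `H`, `E`, `C`.
#' @param pssm_signal strength of the true-residue log-odds signal in
#'   `[0, 1]`; 0 removes all residue identity information from the
#'   PSSM.
#' @param ss_confusion fraction of noise mixed into the one-hot
#'   secondary-structure probabilities; 0 gives the exact one-hot truth.
#' @param sa_error probability that the accessibility track contradicts
#'   the underlying two-state label.
#' @param diso_noise standard deviation of the disorder-probability
#'   noise.
#' @param seed integer seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chains = 30, length_range = c(50, 120),
                             seg_length = c(H = 9, E = 6, C = 5),
                             pssm_signal = 0.8, ss_confusion = 0.15,
                             sa_error = 0.1, diso_noise = 0.05, seed = 1) {
  stopifnot(n_chains >= 0, length(length_range) == 2,
            length_range[1] >= 10, length_range[2] >= length_range[1],
            pssm_signal >= 0, pssm_signal <= 1,
            ss_confusion >= 0, ss_confusion <= 1,
            sa_error >= 0, sa_error <= 1, diso_noise >= 0)
  structure(
    list(n_chains = n_chains, length_range = length_range,
         seg_length = seg_length, pssm_signal = pssm_signal,
         ss_confusion = ss_confusion, sa_error = sa_error,
         diso_noise = diso_noise, seed = seed),
    class = "synthetic_config")
}

# Per-secondary-structure amino-acid propensities (relative weights over
# the alphabetical 20-letter alphabet).
aa_weights_for_ss <- function(ss) {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  boost <- switch(ss,
    H = c(A = 3, E = 2.5, L = 3, K = 2, Q = 2, M = 1.8, R = 1.5),
    E = c(V = 3, I = 2.8, F = 2, Y = 1.8, T = 1.5, W = 1.3, C = 1.3),
    C = c(G = 3, P = 2.8, S = 2, N = 1.8, D = 1.8))
  w[names(boost)] <- boost
  w / sum(w)
}

# One draw from a two-component wrapped-normal-style mixture.
rmix <- function(n, means, sds, weights) {
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  wrap_angle(rnorm(n, means[comp], sds[comp]))
}

sample_phi <- function(aa, ss) {
  n <- length(aa)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    phi[i] <-
      if (aa[i] == "P") rmix(1, -75, 10, 1)
      else if (aa[i] == "G" && ss[i] == "C") rmix(1, c(-90, 90), c(40, 40),
                                                  c(0.5, 0.5))
      else switch(ss[i],
        H = rmix(1, -63, 8, 1),
        E = rmix(1, -120, 20, 1),
        C = rmix(1, c(-85, 75), c(35, 40), c(0.8, 0.2)))
  }
  phi
}

sample_psi <- function(aa, ss) {
  n <- length(aa)
  psi <- numeric(n)
  for (i in seq_len(n)) {
    psi[i] <- switch(ss[i],
      H = rmix(1, -42, 10, 1),
      E = rmix(1, 135, 20, 1),
      C = rmix(1, c(140, -20), c(35, 40), c(0.55, 0.45)))
  }
  psi
}

sample_ss_string <- function(nres, seg_length) {
  states <- character(0)
  state <- sample(c("C", "H", "E"), 1, prob = c(0.6, 0.25, 0.15))
  while (length(states) < nres) {
    len <- 1 + stats::rpois(1, max(seg_length[[state]] - 1, 0.5))
    states <- c(states, rep(state, len))
    state <- if (state == "C") {
      sample(c("H", "E"), 1, prob = c(0.55, 0.45))
    } else {
      "C"
    }
  }
  states[seq_len(nres)]
}

HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Generate one synthetic chain
#'
#' Samples a secondary-structure segment string, amino acids with
#' SS-biased composition, torsion angles from the per-SS (and
#' residue-specific) mixtures, and the four correlated profile tracks.
#' phi of the first residue and psi of the last are undefined, matching
#' real chains.
#'
#' @param config a [synthetic_config()].
#' @param id chain identifier.
#' @param seed optional seed; when given the chain is reproduced
#'   byte-identically.
#' @return a list with `id`, `seq`, `angles` (per-residue tibble with
#'   `pos`, `aa`, `resname`, `ss`, `sa`, `disorder`, `phi`, `psi`) and
#'   `bundle` (a [profile_bundle()]).
#' @export
generate_chain <- function(config = synthetic_config(), id = "S001",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nres <- sample(seq(config$length_range[1], config$length_range[2]), 1)
  ss <- sample_ss_string(nres, config$seg_length)
  aa <- vapply(ss, function(s) {
    w <- aa_weights_for_ss(s)
    sample(AA_ALPHABET, 1, prob = w)
  }, character(1), USE.NAMES = FALSE)
  phi <- sample_phi(aa, ss)
  psi <- sample_psi(aa, ss)
  phi[1] <- NA_real_
  psi[nres] <- NA_real_

  # true two-state accessibility from a hydrophobicity rule
  p_buried <- ifelse(aa %in% HYDROPHOBIC, 0.75, 0.25)
  sa_true <- ifelse(runif(nres) < p_buried, "B", "E")

  # PSSM: integer log-odds, strong on the true residue column
  raw <- matrix(round(rnorm(nres * 20, -2, 1.8)), nrow = nres,
                dimnames = list(NULL, PSSM_ALPHABET))
  true_col <- match(aa, PSSM_ALPHABET)
  raw[cbind(seq_len(nres), true_col)] <-
    round(rnorm(nres, 2 + 6 * config$pssm_signal, 1.2))
  pssm <- structure(list(letters = aa, raw = raw, normalized = raw / 10),
                    class = "pssm_profile")

  # secondary-structure probabilities: one-hot truth mixed with noise
  onehot <- matrix(0, nres, 3, dimnames = list(NULL, c("H", "E", "C")))
  onehot[cbind(seq_len(nres), match(ss, c("H", "E", "C")))] <- 1
  probs <- onehot
  if (config$ss_confusion > 0) {
    noise <- matrix(runif(nres * 3), nres, 3)
    noise <- noise / rowSums(noise)
    probs <- (1 - config$ss_confusion) * onehot + config$ss_confusion * noise
    probs <- round(probs, 3)
  }
  state <- apply(probs, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) "C" else c("H", "E", "C")[top]
  })
  ssp <- structure(list(letters = aa, state = unname(state), probs = probs),
                   class = "ss_profile")

  # accessibility track: true label, contradicted at the error rate
  flip <- runif(nres) < config$sa_error
  sa_track <- ifelse(flip, ifelse(sa_true == "B", "E", "B"), sa_true)
  sa <- structure(
    list(state = sa_track,
         encoding = cbind(exposed = as.numeric(sa_track == "E"),
                          buried = as.numeric(sa_track == "B"))),
    class = "sa_profile")

  # disorder: elevated in coil and at the termini
  terminal <- seq_len(nres) <= 5 | seq_len(nres) > nres - 5
  p_dis <- 0.05 + 0.25 * (ss == "C") + 0.35 * terminal +
    rnorm(nres, 0, config$diso_noise)
  p_dis <- round(pmin(pmax(p_dis, 0), 1), 3)
  diso <- structure(
    list(p_disordered = p_dis, p_ordered = 1 - p_dis,
         encoding = cbind(disordered = p_dis, ordered = 1 - p_dis)),
    class = "disorder_profile")

  seq <- paste(aa, collapse = "")
  angles <- tibble(
    pos = seq_len(nres),
    aa = aa,
    resname = unname(AA_THREE[aa]),
    ss = ss,
    sa = sa_true,
    disorder = ifelse(p_dis >= 0.5, "D", "O"),
    phi = round(phi, 4),
    psi = round(psi, 4))
  list(id = id, seq = seq, angles = angles,
       bundle = profile_bundle(id, seq, pssm, ssp, sa, diso))
}

#' Generate a synthetic dataset
#'
#' @param config a [synthetic_config()]; `config$seed` makes the whole
#'   dataset deterministic.
#' @return an object of class `synthetic_dataset`: list with `chains`
#'   (each as in [generate_chain()]) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  ids <- sprintf("S%03d", seq_len(config$n_chains))
  chains <- lapply(ids, function(id) generate_chain(config, id = id))
  structure(list(chains = chains, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  nres <- sum(vapply(x$chains, function(ch) nchar(ch$seq), numeric(1)))
  cat(sprintf("<synthetic_dataset> %d chains, %d residues (seed %d)\n",
              length(x$chains), nres, x$config$seed))
  invisible(x)
}

#' Pool all per-residue angle records of a dataset
#'
#' @param dataset a `synthetic_dataset` (or plain list of chains).
#' @return a tibble of all chains' angle records with a `chain` column.
#' @export
dataset_records <- function(dataset) {
  chains <- if (inherits(dataset, "synthetic_dataset")) dataset$chains
            else dataset
  bind_rows(lapply(chains, function(ch) {
    mutate(ch$angles, chain = ch$id, .before = 1)
  }))
}

#' Write a dataset as fixture files
#'
#' Writes one FASTA of all sequences, per-chain PSSM / ss2 /
#' accessibility / disorder files in the dialects of [read_pssm()] and
#' friends, per-chain phi and psi angle tables in the 8-column dialect
#' (one angle per table), a `normalizer.txt` with the mean/SD constants
#' used for the normalized column, and a `manifest.tsv` listing chains.
#' [read_dataset_dir()] reproduces the dataset from the files.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param norm optional [fit_angle_normalizer()]; fitted on the dataset
#'   when `NULL`.
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(dataset, dir, norm = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- dataset_records(dataset)
  norm <- norm %||% fit_angle_normalizer(rec$phi, rec$psi)

  fasta <- unlist(lapply(dataset$chains, function(ch) {
    c(paste0(">", ch$id), ch$seq)
  }))
  writeLines(fasta, file.path(dir, "sequences.fasta"))

  for (ch in dataset$chains) {
    write_pssm_file(ch$bundle$pssm, file.path(dir, paste0(ch$id, ".pssm")))
    write_ss2_file(ch$bundle$ss, file.path(dir, paste0(ch$id, ".ss2")))
    write_acc_file(ch$bundle$sa, file.path(dir, paste0(ch$id, ".acc")))
    write_diso_file(ch$bundle$diso, ch$seq,
                    file.path(dir, paste0(ch$id, ".diso")))
    for (ang in c("phi", "psi")) {
      defined <- !is.na(ch$angles[[ang]])
      rows <- tibble(
        resname = ch$angles$resname[defined],
        chain = ch$id,
        pos = as.character(ch$angles$pos[defined]),
        observed = ch$angles[[ang]][defined],
        normalized = normalize_angle(ch$angles[[ang]][defined], ang, norm),
        ss = ch$angles$ss[defined],
        sa = ch$angles$sa[defined],
        disorder = ch$angles$disorder[defined])
      write_angle_table(rows, file.path(dir, paste0(ch$id, ".", ang, ".tsv")),
                        angle = ang)
    }
  }
  writeLines(c(
    sprintf("span\t%.10g", norm$span),
    sprintf("mu_phi\t%.10g", norm$mu[["phi"]]),
    sprintf("sigma_phi\t%.10g", norm$sigma[["phi"]]),
    sprintf("mu_psi\t%.10g", norm$mu[["psi"]]),
    sprintf("sigma_psi\t%.10g", norm$sigma[["psi"]])),
    file.path(dir, "normalizer.txt"))
  manifest <- vapply(dataset$chains, function(ch) {
    sprintf("%s\t%d", ch$id, nchar(ch$seq))
  }, character(1))
  writeLines(c("id\tn_res", manifest, sprintf("# seed\t%d",
                                              dataset$config$seed)),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

write_pssm_file <- function(pssm, path) {
  header <- c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("            ", paste(sprintf("%3s", PSSM_ALPHABET),
                                 collapse = " ")))
  rows <- vapply(seq_len(nrow(pssm$raw)), function(i) {
    paste0(sprintf("%5d %s  ", i, pssm$letters[i]),
           paste(sprintf("%3d", pssm$raw[i, ]), collapse = " "),
           "  ", paste(rep("0", 20), collapse = " "), "  0.00 0.00")
  }, character(1))
  writeLines(c(header, rows), path)
}

write_ss2_file <- function(ss, path) {
  rows <- vapply(seq_len(nrow(ss$probs)), function(i) {
    sprintf("%4d %s %s  %6.3f %6.3f %6.3f", i, ss$letters[i], ss$state[i],
            ss$probs[i, "C"], ss$probs[i, "H"], ss$probs[i, "E"])
  }, character(1))
  writeLines(c("# PSIPRED VFORMAT (mock)", rows), path)
}

write_acc_file <- function(sa, path) {
  s <- paste(tolower(sa$state), collapse = "")
  writeLines(substring(s, seq(1, nchar(s), 60),
                       pmin(seq(1, nchar(s), 60) + 59, nchar(s))), path)
}

write_diso_file <- function(diso, seq, path) {
  letters <- strsplit(seq, "")[[1]]
  rows <- sprintf("%5d %s %s %.3f", seq_along(letters), letters,
                  ifelse(diso$p_disordered >= 0.5, "*", "."),
                  diso$p_disordered)
  writeLines(c("# mock disorder predictions", rows), path)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir a directory written by [write_fixture_files()].
#' @return a `synthetic_dataset`-shaped object (without the generator
#'   config) whose chains carry `bundle` and `angles` and can be passed
#'   to [train_cascade()].
#' @export
read_dataset_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort(paste0("no manifest.tsv in ", dir), class = "phipsi_io_error")
  }
  lines <- read_nonempty_lines(manifest_path)
  lines <- lines[!grepl("^#", lines)][-1]
  ids <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  chains <- lapply(ids, function(id) {
    seq <- seqs$seq[seqs$id == id]
    if (length(seq) != 1) {
      abort(sprintf("chain %s missing from sequences.fasta", id),
            class = "phipsi_consistency_error")
    }
    bundle <- read_profile_bundle(
      id,
      pssm = file.path(dir, paste0(id, ".pssm")),
      ss2 = file.path(dir, paste0(id, ".ss2")),
      acc = file.path(dir, paste0(id, ".acc")),
      diso = file.path(dir, paste0(id, ".diso")),
      seq = seq)
    nres <- nchar(seq)
    angles <- tibble(pos = seq_len(nres),
                     aa = strsplit(seq, "")[[1]],
                     resname = unname(AA_THREE[strsplit(seq, "")[[1]]]),
                     ss = NA_character_, sa = NA_character_,
                     disorder = NA_character_,
                     phi = NA_real_, psi = NA_real_)
    for (ang in c("phi", "psi")) {
      tab_path <- file.path(dir, paste0(id, ".", ang, ".tsv"))
      if (file.exists(tab_path)) {
        tab <- read_angle_table(tab_path, angle = ang)
        idx <- as.integer(tab$pos)
        angles[[ang]][idx] <- tab$observed
        angles$ss[idx] <- tab$ss
        angles$sa[idx] <- tab$sa
        angles$disorder[idx] <- tab$disorder
      }
    }
    list(id = id, seq = seq, angles = angles, bundle = bundle)
  })
  structure(list(chains = chains, config = NULL),
            class = "synthetic_dataset")
}
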