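## Readers and writers for the per-residue profile dialects produced by
## the upstream sequence-analysis tools, plus the 8-column per-residue
## angle-table dialect used for training/test sets.

#' Read a FASTA file of amino-acid sequences
#'
#' Sequences are uppercased and any letter outside the 20 standard amino
#' acids is mapped to `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "phipsi_io_error")
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(cnd) {
      abort(paste0("cannot parse FASTA: ", conditionMessage(cnd)),
            class = "phipsi_format_error")
    })
  if (length(set) == 0) {
    abort("FASTA file contains no records", class = "phipsi_format_error")
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort("FASTA record with empty sequence", class = "phipsi_format_error")
  }
  cleaned <- vapply(seqs, clean_sequence, character(1), USE.NAMES = FALSE)
  # keep only the first whitespace-delimited token of the header
  ids <- sub("\\s.*$", "", names(set))
  tibble(id = ids, seq = cleaned)
}

clean_sequence <- function(s) {
  letters <- strsplit(s, "")[[1]]
  bad <- !(letters %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    warn(sprintf("%d non-standard residue letter(s) (%s) mapped to X",
                 sum(bad), paste(unique(letters[bad]), collapse = ",")))
    letters[bad] <- "X"
  }
  paste(letters, collapse = "")
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Expects the `-Q` ASCII layout: header lines, then one row per residue
#' starting with the residue index and letter followed by the 20 log-odds
#' scores (the trailing percentage block and per-row statistics are
#' ignored).  Scores are divided by 10 so that most values fall in
#' `[0, 1]`; values outside that interval are kept as-is.
#'
#' @param path path to the PSSM file.
#' @param seq_length optional expected number of residues; a mismatch is
#'   an error.
#' @return a `pssm_profile` object: list with `letters` (residue
#'   letters), `raw` and `normalized` (`L x 20` matrices, PSI-BLAST
#'   column order A R N D C Q E G H I L K M F P S T W Y V).
#' @export
read_pssm <- function(path, seq_length = NULL) {
  lines <- read_nonempty_lines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  is_row <- vapply(toks, function(x) {
    length(x) >= 22 && grepl("^[0-9]+$", x[1]) && grepl("^[A-Za-z]$", x[2])
  }, logical(1))
  rows <- toks[is_row]
  if (length(rows) == 0) {
    abort("no PSSM data rows found", class = "phipsi_format_error")
  }
  raw <- matrix(NA_real_, nrow = length(rows), ncol = 20,
                dimnames = list(NULL, PSSM_ALPHABET))
  letters <- character(length(rows))
  for (i in seq_along(rows)) {
    letters[i] <- toupper(rows[[i]][2])
    vals <- suppressWarnings(as.numeric(rows[[i]][3:22]))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric PSSM cell in data row %d", i),
            class = "phipsi_format_error")
    }
    raw[i, ] <- vals
  }
  if (!is.null(seq_length) && length(rows) != seq_length) {
    abort(sprintf("PSSM has %d rows but the sequence has %d residues",
                  length(rows), seq_length),
          class = "phipsi_consistency_error")
  }
  structure(list(letters = letters, raw = raw, normalized = raw / 10),
            class = "pssm_profile")
}

#' Read a PSIPRED .ss2 secondary-structure file
#'
#' The ss2 dialect is a comment header followed by rows
#' `idx letter state pC pH pE`.  Probabilities are re-ordered to
#' (H, E, C) internally; the state letter from the file is preserved.
#'
#' @param path path to the `.ss2` file.
#' @return an `ss_profile` object: list with `letters`, `state`
#'   (per-residue `"H"`, `"E"` or `"C"`) and `probs` (`L x 3` matrix,
#'   columns `H`, `E`, `C`).
#' @export
read_psipred_ss2 <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  is_row <- vapply(toks, function(x) length(x) >= 6 && grepl("^[0-9]+$", x[1]),
                   logical(1))
  rows <- toks[is_row]
  if (length(rows) == 0) {
    abort("no ss2 data rows found", class = "phipsi_format_error")
  }
  bad <- vapply(rows, function(x) !grepl("^[A-Za-z]$", x[3]), logical(1))
  if (any(bad)) {
    abort("ss2 row lacking the state column", class = "phipsi_format_error")
  }
  probs <- matrix(NA_real_, nrow = length(rows), ncol = 3,
                  dimnames = list(NULL, c("H", "E", "C")))
  letters <- character(length(rows))
  state <- character(length(rows))
  for (i in seq_along(rows)) {
    letters[i] <- toupper(rows[[i]][2])
    state[i] <- toupper(rows[[i]][3])
    p <- suppressWarnings(as.numeric(rows[[i]][4:6]))   # file order: C H E
    if (anyNA(p)) {
      abort(sprintf("non-numeric ss2 probability in row %d", i),
            class = "phipsi_format_error")
    }
    probs[i, ] <- c(p[2], p[3], p[1])
  }
  if (any(probs < 0 | probs > 1)) {
    abort("ss2 probabilities outside [0, 1]", class = "phipsi_format_error")
  }
  structure(list(letters = letters, state = state, probs = probs),
            class = "ss_profile")
}

#' Read a two-state solvent-accessibility track
#'
#' Accepts either a bare string of per-residue letters (possibly folded
#' over several lines) or a per-line table whose last letter token is the
#' state; letters are `e`/`E` (exposed) and `b`/`B` (buried).
#'
#' @param path path to the accessibility file.
#' @return an `sa_profile` object: list with `state` (per-residue
#'   `"E"`/`"B"`) and `encoding` (`L x 2` one-hot matrix, columns
#'   `exposed`, `buried`).
#' @export
read_accessibility <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!grepl("^\\s*[#>]", lines)]
  if (length(lines) == 0) {
    abort("empty accessibility file", class = "phipsi_format_error")
  }
  toks <- strsplit(trimws(lines), "\\s+")
  letters <- unlist(lapply(toks, function(x) {
    lt <- x[grepl("^[A-Za-z]$", x)]
    if (length(lt) > 0) {
      # per-line table: last single-letter token is the state
      tail(lt, 1)
    } else {
      # folded string of states
      strsplit(paste(x, collapse = ""), "")[[1]]
    }
  }))
  letters <- toupper(letters)
  bad <- !(letters %in% c("E", "B"))
  if (any(bad)) {
    abort(sprintf("unknown accessibility letter(s): %s",
                  paste(unique(letters[bad]), collapse = ",")),
          class = "phipsi_format_error")
  }
  enc <- cbind(exposed = as.numeric(letters == "E"),
               buried = as.numeric(letters == "B"))
  structure(list(state = letters, encoding = enc), class = "sa_profile")
}

#' Read a per-residue disorder-probability track
#'
#' Accepts a documented superset of the disorder-predictor per-line
#' outputs: each data row carries a residue index and/or letter, an
#' optional order/disorder mark (`*` or `.`), and the disorder
#' probability as its last numeric field.  The ordered probability is
#' taken as the complement when not given.
#'
#' @param path path to the disorder file.
#' @return a `disorder_profile` object: list with `p_disordered` and
#'   `p_ordered` vectors and `encoding` (`L x 2` matrix, columns
#'   `disordered`, `ordered`).
#' @export
read_disorder <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0) {
    abort("empty disorder file", class = "phipsi_format_error")
  }
  toks <- strsplit(trimws(lines), "\\s+")
  p <- vapply(toks, function(x) {
    # a leading bare integer is the residue index, not a probability
    if (length(x) > 1 && grepl("^[0-9]+$", x[1])) x <- x[-1]
    num <- suppressWarnings(as.numeric(x))
    num <- num[!is.na(num) & num >= 0 & num <= 1]
    if (length(num) == 0) NA_real_ else tail(num, 1)
  }, numeric(1))
  if (anyNA(p)) {
    abort("disorder row without a probability in [0, 1]",
          class = "phipsi_format_error")
  }
  structure(list(p_disordered = p, p_ordered = 1 - p,
                 encoding = cbind(disordered = p, ordered = 1 - p)),
            class = "disorder_profile")
}

#' Read / write the 8-column per-residue angle table
#'
#' The dialect carries, per residue and for a single angle type
#' (phi or psi), tab-separated columns: residue name (3-letter), chain
#' name, author residue position, observed angle (degrees), normalized
#' angle (unitless), secondary-structure label, solvent-accessibility
#' label (`E`/`B`) and a disorder label.
#'
#' @param path file path.
#' @param rows a data frame with columns `resname`, `chain`, `pos`,
#'   `observed`, `normalized`, `ss`, `sa`, `disorder`.
#' @param angle which angle the table stores (metadata only).
#' @return `read_angle_table()` returns a tibble with the eight columns
#'   above (attribute `"angle"` set when known); `write_angle_table()`
#'   returns `path` invisibly.  Writing then reading reproduces the
#'   parsed fields.
#' @export
read_angle_table <- function(path, angle = NULL) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate whitespace-separated variants
  toks <- lapply(toks, function(x) {
    if (length(x) == 1) strsplit(trimws(x), "\\s+")[[1]] else x
  })
  nfield <- lengths(toks)
  if (any(nfield != 8)) {
    bad <- which(nfield != 8)[1]
    abort(sprintf("angle table line %d has %d columns (expected 8)",
                  bad, nfield[bad]),
          class = "phipsi_format_error")
  }
  m <- do.call(rbind, toks)
  out <- tibble(
    resname = m[, 1],
    chain = m[, 2],
    pos = m[, 3],
    observed = as.numeric(m[, 4]),
    normalized = as.numeric(m[, 5]),
    ss = m[, 6],
    sa = m[, 7],
    disorder = m[, 8])
  if (anyNA(out$observed) || anyNA(out$normalized)) {
    abort("non-numeric angle value in angle table",
          class = "phipsi_format_error")
  }
  attr(out, "angle") <- angle
  out
}

#' @rdname read_angle_table
#' @export
write_angle_table <- function(rows, path, angle = NULL) {
  need <- c("resname", "chain", "pos", "observed", "normalized",
            "ss", "sa", "disorder")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("angle table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  lines <- sprintf("%s\t%s\t%s\t%.6f\t%.8f\t%s\t%s\t%s",
                   rows$resname, rows$chain, rows$pos,
                   rows$observed, rows$normalized,
                   rows$ss, rows$sa, rows$disorder)
  writeLines(lines, path)
  invisible(path)
}

#' Check observed/normalized consistency of an angle table
#'
#' @param tab a tibble from [read_angle_table()].
#' @param norm an [fit_angle_normalizer()].
#' @param angle `"phi"` or `"psi"`.
#' @param tol absolute tolerance on the normalized values.
#' @return `TRUE` invisibly; aborts when any row is inconsistent.
#' @export
check_angle_table <- function(tab, norm, angle = c("phi", "psi"),
                              tol = 1e-4) {
  angle <- match.arg(angle)
  expected <- normalize_angle(tab$observed, angle, norm)
  off <- which(abs(expected - tab$normalized) > tol)
  if (length(off) > 0) {
    abort(sprintf(
      "%d angle-table row(s) have normalized values inconsistent with the normalizer (first: row %d)",
      length(off), off[1]),
      class = "phipsi_consistency_error")
  }
  invisible(TRUE)
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "phipsi_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("empty file: ", path), class = "phipsi_format_error")
  }
  lines
}
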