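# Shared fixtures, built in code.

# A tiny deterministic bundle with recognisable track values, for
# encoding tests: pssm cell (i, j) = i + j/100, ss prob rows are
# (0.7, 0.2, 0.1) rotations, alternating accessibility, linearly
# increasing disorder.
make_toy_bundle <- function(seq = "ACDEFGHIKL") {
  n <- nchar(seq)
  aa <- strsplit(seq, "")[[1]]
  raw <- outer(seq_len(n), seq_len(20), function(i, j) i + j / 100)
  colnames(raw) <- phipsi:::PSSM_ALPHABET
  pssm <- structure(list(letters = aa, raw = raw, normalized = raw / 10),
                    class = "pssm_profile")
  probs <- matrix(rep(c(0.7, 0.2, 0.1), n), ncol = 3, byrow = TRUE,
                  dimnames = list(NULL, c("H", "E", "C")))
  ssp <- structure(list(letters = aa, state = rep("H", n), probs = probs),
                   class = "ss_profile")
  sa_state <- rep(c("E", "B"), length.out = n)
  sa <- structure(list(state = sa_state,
                       encoding = cbind(exposed = as.numeric(sa_state == "E"),
                                        buried = as.numeric(sa_state == "B"))),
                  class = "sa_profile")
  p <- seq_len(n) / (n + 1)
  diso <- structure(list(p_disordered = p, p_ordered = 1 - p,
                         encoding = cbind(disordered = p, ordered = 1 - p)),
                    class = "disorder_profile")
  profile_bundle("toy", seq, pssm, ssp, sa, diso)
}

# Study-scale cascade fixture: 30 training and 10 test chains at the
# default noise levels, trained once per test run and memoised.
cascade_fixture_env <- new.env(parent = emptyenv())

cascade_fixture <- function() {
  if (is.null(cascade_fixture_env$fix)) {
    train_ds <- generate_dataset(synthetic_config(n_chains = 30, seed = 1))
    test_ds <- generate_dataset(synthetic_config(n_chains = 10, seed = 2))
    model <- train_cascade(train_ds, cascade_config(seed = 1))
    preds <- predict(model, lapply(test_ds$chains, `[[`, "bundle"))
    cascade_fixture_env$fix <- list(
      train = train_ds, test = test_ds, model = model, preds = preds,
      train_rec = dataset_records(train_ds),
      test_rec = dataset_records(test_ds))
  }
  cascade_fixture_env$fix
}

# Small fast dataset for unit tests.
small_dataset <- function(n_chains = 4, seed = 7) {
  generate_dataset(synthetic_config(n_chains = n_chains,
                                    length_range = c(40, 60), seed = seed))
}
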