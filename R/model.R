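## The two-level epsilon-SVR cascade.  Level 1 regresses the normalized
## angle on the sliding-window profile features; level 2 regresses the
## same target on a window of neighbouring level-1 predictions along the
## chain, capturing the local continuity of backbone torsions.

#' SVR hyperparameters
#'
#' Defaults are the RBF-kernel operating point used for both cascade
#' levels: cost `C = 5.0`, tube width `epsilon = 0.01`, kernel width
#' `gamma = 0.01`.
#'
#' @param cost regularization constant C.
#' @param epsilon insensitive-tube half width.
#' @param gamma RBF kernel width.
#' @return a named list of class `svr_hyperparams`.
#' @export
svr_hyperparams <- function(cost = 5.0, epsilon = 0.01, gamma = 0.01) {
  stopifnot(cost > 0, epsilon > 0, gamma > 0)
  structure(list(cost = cost, epsilon = epsilon, gamma = gamma),
            class = "svr_hyperparams")
}

#' Fit the first-level SVR
#'
#' @param X numeric feature matrix (rows = residues).
#' @param y normalized target angles, length `nrow(X)`.
#' @param params an [svr_hyperparams()] object.
#' @param seed integer seed (the solver is deterministic; the seed is
#'   set for strictness).
#' @return a fitted [e1071::svm] epsilon-regression object.
#' @export
train_first_level <- function(X, y, params = svr_hyperparams(), seed = 1) {
  if (nrow(X) != length(y)) {
    abort("feature rows and targets differ in length",
          class = "phipsi_consistency_error")
  }
  if (length(y) < 2) {
    abort("need at least two training rows", class = "phipsi_config_error")
  }
  if (length(unique(y)) == 1) {
    # every target inside one epsilon-tube: the optimal regressor is the
    # constant and the solver has no support vectors to return
    return(structure(list(value = y[1], tot.nSV = 0L),
                     class = "phipsi_constant_fit"))
  }
  set.seed(seed)
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = params$cost, epsilon = params$epsilon,
             gamma = params$gamma, scale = FALSE)
}

#' @export
predict.phipsi_constant_fit <- function(object, newdata, ...) {
  rep(object$value, nrow(as.matrix(newdata)))
}

#' Contextual inputs for the second level
#'
#' Each residue's second-level input is the window of `L2 = 2 * refine_l
#' + 1` level-1 predictions centred on it, zero-padded at the chain
#' ends.  `refine_l = 0` reduces to the identity context.
#'
#' @param predictions level-1 normalized predictions, ordered along the
#'   chain.
#' @param refine_l half window size of the refinement window.
#' @return numeric matrix with `length(predictions)` rows and `L2`
#'   columns.
#' @export
build_second_level_inputs <- function(predictions, refine_l = 4) {
  stopifnot(refine_l >= 0)
  n <- length(predictions)
  L2 <- 2L * refine_l + 1L
  padded <- c(numeric(refine_l), predictions, numeric(refine_l))
  Z <- matrix(0, nrow = n, ncol = L2)
  for (i in seq_len(n)) {
    Z[i, ] <- padded[i:(i + 2L * refine_l)]
  }
  Z
}

#' Fit the second-level SVR on contextual windows
#'
#' @param predictions level-1 normalized predictions along one chain, or
#'   a pre-built context matrix from [build_second_level_inputs()].
#' @inheritParams train_first_level
#' @param refine_l half window size for the context.
#' @return a fitted [e1071::svm] object.
#' @export
train_second_level <- function(predictions, y, refine_l = 4,
                               params = svr_hyperparams(), seed = 1) {
  Z <- if (is.matrix(predictions)) predictions
       else build_second_level_inputs(predictions, refine_l)
  train_first_level(Z, y, params = params, seed = seed)
}

#' Cascade training configuration
#'
#' Defaults follow the best per-angle operating points: phi uses scheme
#' `PB+PP`, psi uses `PB+PP+SC`, both with window length `L = 9`
#' (`l = 4`), and the refinement window defaults to the level-1 window.
#'
#' @param phi_scheme,psi_scheme encoding schemes per angle.
#' @param l half window size of the level-1 window.
#' @param refine_l half window size of the level-2 context window
#'   (default: same as `l`).
#' @param params [svr_hyperparams()].
#' @param span normalization span in standard deviations.
#' @param cap_rows subsampling cap on level-1 training rows; kernel SVR
#'   training is quadratic in rows, so desk-scale runs cap the design
#'   (rows are chosen with the seed; raise the cap for full-scale runs).
#' @param seed integer seed controlling subsampling.
#' @param angles which angle types to train.
#' @param extra_trim extra residues excluded at each terminus.
#' @param global_width `ALL`-scheme global block width.
#' @param oof_folds 0 to train level 2 on in-sample level-1 predictions
#'   (default); `k >= 2` for chain-level k-fold out-of-fold level-1
#'   predictions, reducing leakage between the levels.
#' @return a list of class `cascade_config`.
#' @export
cascade_config <- function(phi_scheme = "PB+PP", psi_scheme = "PB+PP+SC",
                           l = 4, refine_l = NULL,
                           params = svr_hyperparams(), span = 6,
                           cap_rows = 20000, seed = 1,
                           angles = c("phi", "psi"), extra_trim = 0,
                           global_width = 22, oof_folds = 0) {
  stopifnot(cap_rows >= 1, l >= 1, extra_trim >= 0)
  angles <- match.arg(angles, several.ok = TRUE)
  structure(
    list(scheme = list(phi = phi_scheme, psi = psi_scheme),
         l = l, refine_l = refine_l %||% l, params = params, span = span,
         cap_rows = cap_rows, seed = seed, angles = angles,
         extra_trim = extra_trim, global_width = global_width,
         oof_folds = oof_folds),
    class = "cascade_config")
}

#' Train the two-level torsion cascade
#'
#' Fits, per angle type: the angle normalizer on all defined training
#' angles, the level-1 SVR on windowed profile features, and the level-2
#' SVR on windows of level-1 predictions along each chain.
#'
#' @param chains a list of chains; each element is a list with `bundle`
#'   (a [profile_bundle()]) and `angles` (per-residue tibble aligned to
#'   the sequence with columns `phi`, `psi`; `NA` = undefined).  A
#'   [generate_dataset()] object can be passed directly.
#' @param config a [cascade_config()].
#' @return an object of class `torsion_cascade`.
#' @export
train_cascade <- function(chains, config = cascade_config()) {
  if (inherits(chains, "synthetic_dataset")) chains <- chains$chains
  stopifnot(length(chains) >= 1)
  all_phi <- unlist(lapply(chains, function(ch) ch$angles$phi))
  all_psi <- unlist(lapply(chains, function(ch) ch$angles$psi))
  norm <- fit_angle_normalizer(all_phi, all_psi, span = config$span)

  fits <- list()
  for (ang in config$angles) {
    scheme <- config$scheme[[ang]]
    enc <- lapply(chains, function(ch) {
      encode_chain(ch$bundle, ch$angles, which = ang, norm = norm,
                   scheme = scheme, l = config$l,
                   extra_trim = config$extra_trim,
                   global_width = config$global_width)
    })
    X <- do.call(rbind, lapply(enc, `[[`, "X"))
    y <- unlist(lapply(enc, `[[`, "y"))
    if (length(y) == 0) {
      abort(sprintf("no defined %s targets in the training chains", ang),
            class = "phipsi_config_error")
    }
    sel <- seq_along(y)
    if (length(y) > config$cap_rows) {
      set.seed(config$seed)
      sel <- sort(sample.int(length(y), config$cap_rows))
    }
    level1 <- train_first_level(X[sel, , drop = FALSE], y[sel],
                                params = config$params, seed = config$seed)

    # level-1 predictions along every full chain feed the context windows
    chain_preds <- level1_chain_predictions(chains, level1, scheme, config,
                                            ang, norm)
    Z <- do.call(rbind, lapply(seq_along(chains), function(i) {
      ctx <- build_second_level_inputs(chain_preds[[i]], config$refine_l)
      ctx[enc[[i]]$index, , drop = FALSE]
    }))
    level2 <- train_first_level(Z[sel, , drop = FALSE], y[sel],
                                params = config$params, seed = config$seed)
    fits[[ang]] <- list(level1 = level1, level2 = level2, scheme = scheme,
                        n_train = length(sel))
  }
  structure(
    list(fits = fits, normalizer = norm, config = config,
         version = 1L,
         trained = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    class = "torsion_cascade")
}

# In-sample (default) or chain-level out-of-fold level-1 predictions for
# every residue of every chain.
level1_chain_predictions <- function(chains, level1, scheme, config, ang,
                                     norm) {
  encode_all <- function(ch) {
    encode_positions(ch$bundle, scheme = scheme, l = config$l,
                     global_width = config$global_width)
  }
  if (config$oof_folds < 2 || length(chains) < config$oof_folds) {
    return(lapply(chains, function(ch) {
      unname(predict(level1, encode_all(ch)))
    }))
  }
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(config$oof_folds), length(chains)))
  preds <- vector("list", length(chains))
  for (f in seq_len(config$oof_folds)) {
    train_idx <- which(fold != f)
    enc <- lapply(chains[train_idx], function(ch) {
      encode_chain(ch$bundle, ch$angles, which = ang, norm = norm,
                   scheme = scheme, l = config$l,
                   extra_trim = config$extra_trim,
                   global_width = config$global_width)
    })
    Xf <- do.call(rbind, lapply(enc, `[[`, "X"))
    yf <- unlist(lapply(enc, `[[`, "y"))
    fit_f <- train_first_level(Xf, yf, params = config$params,
                               seed = config$seed)
    for (i in which(fold == f)) {
      preds[[i]] <- unname(predict(fit_f, encode_all(chains[[i]])))
    }
  }
  preds
}

#' @export
print.torsion_cascade <- function(x, ...) {
  cat("<torsion_cascade>\n")
  for (ang in names(x$fits)) {
    f <- x$fits[[ang]]
    cat(sprintf(
      "  %s: scheme %s, L = %d, refine L2 = %d, %d training rows, SV %d/%d\n",
      ang, f$scheme, 2 * x$config$l + 1, 2 * x$config$refine_l + 1,
      f$n_train, f$level1$tot.nSV, f$level2$tot.nSV))
  }
  print(x$normalizer)
  invisible(x)
}

#' Predict torsion angles for a chain
#'
#' Runs the full cascade: level-1 SVR on windowed features, contextual
#' window of level-1 outputs, level-2 SVR, then denormalization and
#' wrapping into (-180, 180].  Residues whose angle is geometrically
#' undefined (phi of the first residue, psi of the last) and any extra
#' trimmed terminal residues carry `NA`.
#'
#' @param object a `torsion_cascade`.
#' @param bundle a [profile_bundle()] (or list of bundles).
#' @param ... unused.
#' @return a tibble with one row per residue: `id`, `pos` (1-based),
#'   `aa`, and the predicted `phi` and/or `psi` in degrees.
#' @export
predict.torsion_cascade <- function(object, bundle, ...) {
  if (inherits(bundle, "profile_bundle")) {
    return(predict_one_chain(object, bundle))
  }
  bind_rows(lapply(bundle, function(b) predict_one_chain(object, b)))
}

predict_one_chain <- function(model, bundle) {
  stopifnot(inherits(bundle, "profile_bundle"))
  cfg <- model$config
  nres <- nchar(bundle$seq)
  out <- tibble(id = bundle$id, pos = seq_len(nres),
                aa = strsplit(bundle$seq, "")[[1]])
  for (ang in names(model$fits)) {
    f <- model$fits[[ang]]
    X <- encode_positions(bundle, scheme = f$scheme, l = cfg$l,
                          global_width = cfg$global_width)
    p1 <- unname(predict(f$level1, X))
    Z <- build_second_level_inputs(p1, cfg$refine_l)
    p2 <- unname(predict(f$level2, Z))
    pred <- denormalize_angle(p2, ang, model$normalizer)
    undef <- if (ang == "phi") 1L else nres
    pred[undef] <- NA_real_
    if (cfg$extra_trim > 0) {
      trim <- c(seq_len(min(cfg$extra_trim, nres)),
                seq.int(max(1, nres - cfg$extra_trim + 1), nres))
      pred[trim] <- NA_real_
    }
    out[[ang]] <- pred
  }
  out
}

#' Save / load a fitted cascade
#'
#' The archive is a single serialized file plus a plain-text metadata
#' sidecar (`<path>.meta.txt`) recording schemes, windows,
#' hyperparameters, normalizer constants and the seed.
#'
#' @param model a `torsion_cascade`.
#' @param path archive path.
#' @return `save_cascade()` returns `path` invisibly; `load_cascade()`
#'   returns the `torsion_cascade`.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "torsion_cascade"))
  saveRDS(model, path)
  meta <- c(
    sprintf("format_version\t%d", model$version),
    sprintf("angles\t%s", paste(names(model$fits), collapse = ",")),
    vapply(names(model$fits), function(ang) {
      sprintf("scheme_%s\t%s", ang, model$fits[[ang]]$scheme)
    }, character(1)),
    sprintf("l\t%d", model$config$l),
    sprintf("refine_l\t%d", model$config$refine_l),
    sprintf("cost\t%g", model$config$params$cost),
    sprintf("epsilon\t%g", model$config$params$epsilon),
    sprintf("gamma\t%g", model$config$params$gamma),
    sprintf("span\t%g", model$normalizer$span),
    sprintf("mu_phi\t%.10g", model$normalizer$mu[["phi"]]),
    sprintf("sigma_phi\t%.10g", model$normalizer$sigma[["phi"]]),
    sprintf("mu_psi\t%.10g", model$normalizer$mu[["psi"]]),
    sprintf("sigma_psi\t%.10g", model$normalizer$sigma[["psi"]]),
    sprintf("seed\t%d", model$config$seed),
    sprintf("trained\t%s", model$trained))
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("model archive not found: ", path),
          class = "phipsi_io_error")
  }
  model <- readRDS(path)
  if (!inherits(model, "torsion_cascade") || is.null(model$version)) {
    abort("not a torsion cascade archive", class = "phipsi_format_error")
  }
  if (model$version != 1L) {
    abort(sprintf("unsupported model archive version %s", model$version),
          class = "phipsi_format_error")
  }
  model
}

#' @method tidy torsion_cascade
#' @export
tidy.torsion_cascade <- function(x, ...) {
  bind_rows(lapply(names(x$fits), function(ang) {
    f <- x$fits[[ang]]
    tibble(angle = ang, scheme = f$scheme,
           window = 2L * x$config$l + 1L,
           refine_window = 2L * x$config$refine_l + 1L,
           n_train = f$n_train,
           n_sv_level1 = f$level1$tot.nSV,
           n_sv_level2 = f$level2$tot.nSV)
  }))
}

#' @method glance torsion_cascade
#' @export
glance.torsion_cascade <- function(x, ...) {
  tibble(angles = paste(names(x$fits), collapse = ","),
         cost = x$config$params$cost,
         epsilon = x$config$params$epsilon,
         gamma = x$config$params$gamma,
         span = x$normalizer$span,
         cap_rows = x$config$cap_rows,
         seed = x$config$seed)
}
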