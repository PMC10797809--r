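#' The four classical conflict-paradox fixtures
#'
#' The canonical BPA sets on which Dempster's rule fails: complete
#' conflict (k = 1, zero denominator), zero trust (one source vetoes an
#' otherwise well-supported hypothesis), one trust (a hypothesis every
#' source considers unlikely wins outright), and high conflict (strong
#' joint support is discarded). The first three use four sources over
#' hypotheses \{F, G, H\}; the last uses five sources over \{F, G, H, I, J\}.
#'
#' @return A named list of four `evidence_tbl`s:
#'   `complete_conflict`, `zero_trust`, `one_trust`, `high_conflict`.
#' @examples
#' paradox_fixtures()$zero_trust
#' @export
paradox_fixtures <- function() {
  f3 <- ds_frame(c("F", "G", "H"))
  f5 <- ds_frame(c("F", "G", "H", "I", "J"))
  mk <- function(rows, frame) {
    M <- do.call(rbind, rows)
    rownames(M) <- paste0("m", seq_along(rows))
    as_evidence(M, frame = frame)
  }
  list(
    complete_conflict = mk(list(c(1, 0, 0),
                                c(0, 1, 0),
                                c(0.8, 0.1, 0.1),
                                c(0.8, 0.1, 0.1)), f3),
    zero_trust = mk(list(c(0.5, 0.2, 0.3),
                         c(0.5, 0.2, 0.3),
                         c(0, 0.9, 0.1),
                         c(0.5, 0.2, 0.3)), f3),
    one_trust = mk(list(c(0.9, 0.1, 0),
                        c(0, 0.1, 0.9),
                        c(0.1, 0.15, 0.75),
                        c(0.1, 0.15, 0.75)), f3),
    high_conflict = mk(list(c(0.7, 0.1, 0.1, 0, 0.1),
                            c(0, 0.5, 0.2, 0.1, 0.2),
                            c(0.6, 0.1, 0.15, 0, 0.15),
                            c(0.55, 0.1, 0.1, 0.15, 0.1),
                            c(0.6, 0.1, 0.2, 0, 0.1)), f5)
  )
}

#' Class priors of a seven-class fundus-image training corpus
#'
#' The default class imbalance of the synthetic generator: proportions of
#' the seven single-disease fundus classes (Normal, Diabetic retinopathy,
#' Glaucoma, Cataract, AMD, Hypertension, Myopia) in an augmented
#' 25,336-image training corpus with counts
#' N 13,588; D 6,665; G 1,046; C 1,260; AMD 1,138; H 497; M 1,142.
#'
#' @return A named probability vector over the seven classes (sums to 1).
#' @export
fundus_class_priors <- function() {
  counts <- c(N = 13588, D = 6665, G = 1046, C = 1260,
              AMD = 1138, H = 497, M = 1142)
  counts / sum(counts)
}

#' Simulate per-sample softmax outputs from imperfect classifiers
#'
#' A seeded generator emulating the statistical setting of decision-level
#' ensemble fusion: several imperfect classifiers score the same samples
#' over a common frame. True labels are drawn from `priors`. Each source
#' predicts the true class with its target accuracy; errors are uniform
#' over the wrong classes. Under `errors = "independent"` each source errs
#' on its own samples; under `"shared"` all sources err on the same
#' samples (a negative control: fusion gains come from disagreement
#' resolution, so shared errors yield none).
#'
#' Each output row is a simulated softmax vector: the predicted class gets
#' mass `p = concentration / (concentration + 1)` and the residual `1 - p`
#' is spread over the remaining classes by a Dirichlet draw. When a source
#' is correct the residual draw is symmetric; when it errs, the true class
#' receives Dirichlet weight `runner_up_bias` (vs 1 for the others),
#' reproducing the runner-up probability that trained softmax classifiers
#' retain on the true class when they misclassify. That residual signal is
#' what lets fusion outperform each single source; see the package
#' vignette. As `concentration` grows, rows approach one-hot vectors.
#'
#' @param n_samples Number of samples.
#' @param accuracies Per-source target accuracies, each in `(1/n_classes, 1]`;
#'   one source per entry (default two sources at 0.85).
#' @param priors Named class-prior vector (default [fundus_class_priors()]);
#'   the names define the frame.
#' @param errors `"independent"` or `"shared"`.
#' @param concentration Sharpness of the simulated softmax (> 0); the
#'   predicted-class mass is `concentration / (concentration + 1)`,
#'   default 8 (mass 8/9).
#' @param runner_up_bias Dirichlet weight of the true class in the
#'   residual when a source errs (default 4; 1 = no runner-up signal).
#' @param seed Seed fixing all randomness end-to-end; the session RNG
#'   state is restored on exit.
#' @return A list: `truth` (tibble `sample_id`, `label`) and `predictions`
#'   (list of prediction tibbles, one per source, named `m1`, `m2`, ...),
#'   ready for [fuse_predictions()].
#' @examples
#' sim <- gen_predictions(100, accuracies = c(0.85, 0.85), seed = 7)
#' fused <- fuse_predictions(sim$predictions, rule = "idset")
#' mean(fused$decision == sim$truth$label)
#' @export
gen_predictions <- function(n_samples, accuracies = c(0.85, 0.85),
                            priors = fundus_class_priors(),
                            errors = c("independent", "shared"),
                            concentration = 8, runner_up_bias = 4,
                            seed = NULL) {
  errors <- match.arg(errors)
  if (is.null(names(priors))) {
    abort("priors must be named by class label.", class = "evidfuse_spec_error")
  }
  frame <- as_frame(names(priors))
  phi <- length(frame)
  if (abs(sum(priors) - 1) > 1e-8) {
    abort("priors must sum to 1.", class = "evidfuse_spec_error")
  }
  if (n_samples < 1) {
    abort("n_samples must be positive.", class = "evidfuse_spec_error")
  }
  if (any(accuracies <= 1 / phi | accuracies > 1)) {
    abort(sprintf("Accuracies must lie in (1/%d, 1].", phi),
          class = "evidfuse_spec_error")
  }
  if (concentration <= 0 || runner_up_bias <= 0) {
    abort("concentration and runner_up_bias must be positive.",
          class = "evidfuse_spec_error")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }

  labs <- unclass(frame)
  truth_idx <- sample.int(phi, n_samples, replace = TRUE, prob = priors)
  ids <- sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))
  p_top <- concentration / (concentration + 1)

  u_shared <- runif(n_samples)
  predictions <- purrr::imap(as.list(accuracies), function(acc, s) {
    u <- if (errors == "shared") u_shared else runif(n_samples)
    correct <- u <= acc
    pred_idx <- truth_idx
    wrong <- which(!correct)
    if (length(wrong)) {
      # uniform over the phi - 1 wrong classes
      shift <- sample.int(phi - 1, length(wrong), replace = TRUE)
      pred_idx[wrong] <- ((truth_idx[wrong] - 1 + shift) %% phi) + 1
    }
    # Dirichlet residual over the non-predicted classes via gamma draws;
    # the true class is upweighted when the source erred.
    W <- matrix(1, n_samples, phi)
    W[cbind(wrong, truth_idx[wrong])] <- runner_up_bias
    G <- matrix(rgamma(n_samples * phi, shape = as.vector(t(W))),
                n_samples, phi, byrow = TRUE)
    G[cbind(seq_len(n_samples), pred_idx)] <- 0
    M <- (1 - p_top) * G / rowSums(G)
    M[cbind(seq_len(n_samples), pred_idx)] <- p_top
    colnames(M) <- labs
    dplyr::bind_cols(tibble(sample_id = ids),
                     as_tibble(M, .name_repair = "minimal"))
  })
  names(predictions) <- paste0("m", seq_along(predictions))

  list(truth = tibble(sample_id = ids, label = labs[truth_idx]),
       predictions = predictions)
}

#' Synthetic RGB test image
#'
#' A seeded random image (smooth per-channel gradients plus noise) for
#' exercising the augmentation pipeline without any real photograph.
#'
#' @param width,height Pixel dimensions.
#' @param seed Optional seed (session RNG state restored on exit).
#' @return An [rgb_image()].
#' @export
gen_image <- function(width = 64, height = 64, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  r <- outer(seq(0, 1, length.out = height), seq(0, 1, length.out = width))
  px <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    px[, , ch] <- pmin(pmax(runif(1) * r + 0.3 * runif(1) +
                              0.2 * matrix(runif(height * width),
                                           height, width), 0), 1)
  }
  rgb_image(px * 255)
}

#' Seeded train/test split
#'
#' Randomly partitions sample indices in a given proportion. When images
#' were augmented before splitting, near-duplicates of one source image
#' can land on both sides of the split and test scores become optimistic
#' (leakage); set `after_augmentation = TRUE` to acknowledge such a
#' workflow and get an explicit warning.
#'
#' @param n Number of samples (or a vector of ids).
#' @param prop Training proportion (default 0.8).
#' @param seed Optional seed (session RNG state restored on exit).
#' @param after_augmentation Set `TRUE` when splitting an already-augmented
#'   dataset; emits a leakage warning.
#' @return A list with `train` and `test` index (or id) vectors.
#' @export
split_train_test <- function(n, prop = 0.8, seed = NULL,
                             after_augmentation = FALSE) {
  ids <- if (length(n) == 1 && is.numeric(n)) seq_len(n) else n
  if (prop <= 0 || prop >= 1) {
    abort("prop must be in (0, 1).", class = "evidfuse_spec_error")
  }
  if (after_augmentation) {
    warn(paste0("Splitting after augmentation: transformed copies of one ",
                "source image can fall on both sides of the split, ",
                "inflating test scores (leakage)."),
         class = "evidfuse_leakage_warning")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_train <- round(length(ids) * prop)
  tr <- sample(seq_along(ids), n_train)
  list(train = ids[sort(tr)], test = ids[sort(setdiff(seq_along(ids), tr))])
}
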