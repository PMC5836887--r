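# Fingerprint-based activity scoring: ECFP6 fingerprints (extended-
# connectivity, diameter 6), an SVM classifier with Gaussian kernel and
# probability outputs, the two-branch latent-point score S(z), and the
# macrocycle filter used inside the optimization objective.

#' ECFP6 fingerprints
#'
#' Extended-connectivity fingerprints of diameter 6, computed by the
#' chemistry toolkit on the toolkit's 4096-bit space and folded (bitwise OR
#' of the two halves) down to `nbits`. Identical molecules give identical
#' fingerprints regardless of input SMILES notation.
#'
#' @param smiles Character vector of valid SMILES.
#' @param nbits Folded fingerprint length, a power of 2 up to 4096
#'   (default 2048).
#' @return Binary matrix with `length(smiles)` rows and `nbits` columns.
#' @export
fingerprint_ecfp6 <- function(smiles, nbits = 2048L) {
  stopifnot(nbits >= 64, nbits <= 4096, bitwAnd(nbits, nbits - 1L) == 0L)
  ok <- is_valid_smiles(smiles)
  if (any(!ok)) stop("invalid SMILES: ", paste(utils::head(smiles[!ok], 3), collapse = ", "))
  src <- paste0(paste(smiles, paste0("m", seq_along(smiles)), sep = " "),
                collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP6")  # n x 4096 matrix
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)

  while (ncol(fp) > nbits) {
    half <- ncol(fp) / 2
    fp <- pmin(fp[, 1:half, drop = FALSE] +
               fp[, (half + 1):(2 * half), drop = FALSE], 1)
  }
  storage.mode(fp) <- "integer"
  rownames(fp) <- NULL
  fp
}

#' Tanimoto similarity between fingerprint rows
#'
#' |A intersect B| / |A union B| over the set bits of two binary vectors.
#'
#' @param a,b Binary vectors of equal length (e.g. rows of
#'   [fingerprint_ecfp6()]).
#' @return Similarity in \[0, 1\] (1 for two empty fingerprints).
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Train a fingerprint SVM activity model
#'
#' Fits a Gaussian-kernel (radial basis) SVM with probability outputs on
#' ECFP6 fingerprints of a labeled SMILES table. Hyperparameters C and gamma
#' are chosen by cross-validated grid search; classes are weighted inversely
#' to their frequency so imbalanced tables (the common case for bioactivity
#' data) do not collapse to the majority class. A k-fold cross-validated
#' AUROC estimate is computed on the training table.
#'
#' @param data Data frame with columns `smiles` and `label` (0/1; 1 =
#'   active). Both classes must be present.
#' @param nbits Fingerprint length (default 2048).
#' @param cost,gamma Candidate grids for the SVM hyperparameters; defaults
#'   `c(1, 10)` and `1/nbits * c(1, 10, 100)`.
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment.
#' @return An `activity_model`: the fitted SVM, fingerprint spec, the chosen
#'   hyperparameters and the cross-validated AUROC (`$cv_auroc`).
#' @export
train_activity_model <- function(data, nbits = 2048L, cost = c(1, 10),
                                 gamma = NULL, folds = 5L, seed = 1L) {
  stopifnot(all(c("smiles", "label") %in% names(data)))
  y <- as.integer(data$label)
  if (length(unique(y)) < 2L) stop("both an active and an inactive class are required")
  fp <- fingerprint_ecfp6(data$smiles, nbits = nbits)
  if (is.null(gamma)) gamma <- c(1, 10, 100) / nbits
  yf <- factor(y, levels = c(0, 1))
  wts <- 100 / table(yf)

  grid <- expand.grid(cost = cost, gamma = gamma)
  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), length(y)))
    cv_auc <- function(cost, gamma) {
      preds <- numeric(length(y))
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        fit <- e1071::svm(fp[tr, , drop = FALSE], yf[tr], kernel = "radial",
                          cost = cost, gamma = gamma, probability = TRUE,
                          class.weights = wts, scale = FALSE)
        pr <- attr(stats::predict(fit, fp[!tr, , drop = FALSE], probability = TRUE),
                   "probabilities")[, "1"]
        preds[!tr] <- pr
      }
      auroc(preds, y)
    }
    scores <- mapply(cv_auc, grid$cost, grid$gamma)
    best <- which.max(scores)
    fit <- e1071::svm(fp, yf, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], probability = TRUE,
                      class.weights = wts, scale = FALSE)
    structure(
      list(svm = fit, nbits = as.integer(nbits),
           cost = grid$cost[best], gamma = grid$gamma[best],
           cv_auroc = scores[best], threshold = 0.5,
           n_active = sum(y == 1), n_inactive = sum(y == 0)),
      class = "activity_model"
    )
  })
}

# rank-based AUROC (Mann-Whitney), no package dependency needed
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.activity_model <- function(x, ...) {
  cat("<activity_model> ECFP6 SVM (radial),", x$nbits, "bits\n")
  cat(sprintf("  C = %g, gamma = %g; CV AUROC = %.3f; %d actives / %d inactives\n",
              x$cost, x$gamma, x$cv_auroc, x$n_active, x$n_inactive))
  invisible(x)
}

#' @export
glance.activity_model <- function(x, ...) {
  tibble::tibble(nbits = x$nbits, cost = x$cost, gamma = x$gamma,
                 cv_auroc = x$cv_auroc, n_active = x$n_active,
                 n_inactive = x$n_inactive)
}

#' Predict activity probabilities
#'
#' @param object An `activity_model`.
#' @param smiles Character vector of valid SMILES.
#' @param ... Unused.
#' @return Numeric vector of P(active) in \[0, 1\].
#' @export
predict.activity_model <- function(object, smiles, ...) {
  fp <- fingerprint_ecfp6(smiles, nbits = object$nbits)
  pr <- attr(stats::predict(object$svm, fp, probability = TRUE),
             "probabilities")
  unname(pr[, "1"])
}

#' Two-branch activity score for a set of sampled compounds
#'
#' The score of a latent point is the mean P(active) over the sampled
#' compounds classified active (P > 0.5); when no compound crosses the
#' threshold, it falls back to the mean P(active) over all valid compounds,
#' and to 0 when there are no valid compounds at all (so non-decodable
#' latent points rank worst).
#'
#' @param p_active Numeric vector of per-compound activity probabilities
#'   (invalid/filtered compounds already excluded).
#' @param threshold Classification threshold (fixed at 0.5).
#' @return List with `score`, `n_valid`, `n_active`.
#' @export
activity_score_values <- function(p_active, threshold = 0.5) {
  if (length(p_active) == 0L) {
    return(list(score = 0, n_valid = 0L, n_active = 0L))
  }
  act <- p_active > threshold
  score <- if (any(act)) mean(p_active[act]) else mean(p_active)
  list(score = score, n_valid = length(p_active), n_active = sum(act))
}

#' Score a generation report against an activity model
#'
#' Applies the [macrocycle_filter()] to the unique valid sampled compounds,
#' predicts P(active) for the survivors, and combines them with the
#' two-branch rule of [activity_score_values()].
#'
#' @param report A `generation_report` from [generate()].
#' @param model An `activity_model`.
#' @param max_ring Largest allowed ring size (default 8).
#' @param unique_compounds Score each distinct compound once (default
#'   `TRUE`) rather than weighting by sampling frequency.
#' @return A `score_result`: list with `score`, `n_valid`, `n_active` and
#'   `per_smiles` (tibble: smiles, p_active).
#' @export
activity_score <- function(report, model, max_ring = 8L,
                           unique_compounds = TRUE) {
  ft <- report$frequency_table
  keep <- ft[ft$valid & nzchar(ft$smiles), , drop = FALSE]
  if (nrow(keep) > 0) {
    keep <- keep[macrocycle_filter(keep$smiles, max_ring = max_ring), , drop = FALSE]
  }
  if (nrow(keep) == 0) {
    return(structure(list(score = 0, n_valid = 0L, n_active = 0L,
                          per_smiles = tibble::tibble(smiles = character(),
                                                      p_active = numeric())),
                     class = "score_result"))
  }
  p <- predict(model, keep$smiles)
  pvec <- if (unique_compounds) p else rep(p, keep$count)
  res <- activity_score_values(pvec, threshold = model$threshold)
  structure(c(res, list(per_smiles = tibble::tibble(smiles = keep$smiles,
                                                    p_active = p))),
            class = "score_result")
}

#' Macrocycle filter
#'
#' Keeps molecules whose smallest-set-of-smallest-rings contains no ring of
#' more than `max_ring` atoms; an 8-membered ring passes, a 9-membered ring
#' does not. Acyclic molecules always pass.
#'
#' @param smiles Character vector of valid SMILES.
#' @param max_ring Largest allowed ring size (default 8).
#' @return Logical vector: `TRUE` = keep.
#' @export
macrocycle_filter <- function(smiles, max_ring = 8L) {
  largest_ring_size(smiles) <= max_ring
}
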