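# value boundary t such that mean(x <= t) is as close as possible to the
# target share, both sides non-empty
threshold_for_share <- function(x, target) {
  xs <- sort(unique(x))
  if (length(xs) < 2L) return(xs[1L])
  xs <- xs[-length(xs)]
  cdf <- findInterval(xs, sort(x)) / length(x)
  xs[which.min(abs(cdf - target))]
}

#' Configuration for the synthetic drug-combination generator
#'
#' Emulates the structure of drug-combination effect datasets: each drug
#' carries a latent expression-like signature, a sample concatenates the
#' signatures of its two drugs (so v = 2 * signature_dim), and the effect
#' class (Antagonism / Additive / Synergy, Additive-majority) is planted
#' as an axis-aligned interval rule on a few informative coordinates —
#' the hypothesis class multi-branch stumps can represent, making
#' parameter-recovery checks fair. Default class ratios mirror a
#' real-world colorectal screen's imbalance (134/451/140).
#'
#' @param n_drugs number of distinct drugs.
#' @param signature_dim latent per-drug signature length g (dataset has
#'   2g features).
#' @param n_samples number of drug-pair samples.
#' @param class_ratios length-3 target shares for
#'   (Antagonism, Additive, Synergy); must sum to 1.
#' @param n_informative number of rule-bearing coordinates (1 or 2 used
#'   by the planted rule).
#' @param noise_sd standard deviation of additive Gaussian feature noise
#'   (signatures have unit variance).
#' @param nonlinear plant a harder XOR-style synergy condition instead of
#'   a single interval (robustness testing; parameter recovery is no
#'   longer guaranteed for stump-based learners).
#' @param seed integer seed.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_drugs = 40L, signature_dim = 20L,
                         n_samples = 1000L,
                         class_ratios = c(134, 451, 140) / 725,
                         n_informative = 2L, noise_sd = 0.05,
                         nonlinear = FALSE, seed = 1L) {
  stopifnot(n_drugs >= 2L, signature_dim >= 1L, n_samples >= 10L,
            length(class_ratios) == 3L, all(class_ratios > 0),
            abs(sum(class_ratios) - 1) < 1e-8,
            n_informative >= 1L, n_informative <= 2L * signature_dim,
            noise_sd >= 0)
  structure(list(n_drugs = as.integer(n_drugs),
                 signature_dim = as.integer(signature_dim),
                 n_samples = as.integer(n_samples),
                 class_ratios = as.numeric(class_ratios),
                 n_informative = as.integer(n_informative),
                 noise_sd = noise_sd, nonlinear = isTRUE(nonlinear),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic drug-combination dataset
#'
#' Draws standard-normal per-drug signatures, samples drug pairs (every
#' drug appears in at least one sample), concatenates the two signatures
#' into the feature vector, adds Gaussian noise, assigns labels by the
#' planted interval rule on the noise-free values — thresholds are
#' empirical quantiles chosen so marginal class shares match
#' \code{class_ratios} up to the granularity of repeated per-drug values
#' — and min-max scales features into [0, 1]. The ground-truth rule
#' (informative feature indices and thresholds on the scaled axis) is
#' attached as attribute \code{"ground_truth"}.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A \code{\link{labeled_dataset}} with \code{drug_pairs} and a
#'   \code{"ground_truth"} attribute.
#' @examples
#' ds <- generate_synthetic(synth_config(n_samples = 200, seed = 7))
#' table(ds$class_names[ds$labels])
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  g <- config$signature_dim
  n <- config$n_samples
  nd <- config$n_drugs
  class_names <- c("Antagonism", "Additive", "Synergy")
  r <- config$class_ratios

  sig <- matrix(rnorm(nd * g), nd, g)
  drug_ids <- sprintf("drug%03d", seq_len(nd))

  # pairs: first cover every drug once (shuffled consecutive pairing),
  # then uniform random distinct pairs
  perm <- sample.int(nd)
  if (nd %% 2L == 1L) perm <- c(perm, perm[1L])
  cover <- matrix(perm, ncol = 2L, byrow = TRUE)
  n_cover <- nrow(cover)
  if (n_cover > n) stop("n_samples too small to cover every drug")
  extra <- t(replicate(n - n_cover, sample.int(nd, 2L)))
  pairs <- rbind(cover, extra)

  true_x <- cbind(sig[pairs[, 1L], , drop = FALSE],
                  sig[pairs[, 2L], , drop = FALSE])
  v <- 2L * g
  informative <- sort(sample.int(v, config$n_informative))
  f1 <- informative[1L]
  f2 <- if (config$n_informative >= 2L) informative[2L] else f1
  if (config$n_informative > 2L) {
    warning("planted rule uses the first 2 informative features; ",
            "the rest carry no class signal")
  }

  # decision-list rule on noise-free values:
  #   Antagonism if x[f1] <= t1; else Synergy if x[f2] > t2; else Additive
  # Thresholds sit at value boundaries minimizing the deviation of the
  # realized share from the target — feature values repeat per drug, so
  # shares move in drug-sized blocks and a plain quantile can overshoot.
  t1 <- threshold_for_share(true_x[, f1], r[1L])
  labels <- rep(2L, n)                       # Additive
  ant <- true_x[, f1] <= t1
  labels[ant] <- 1L
  rest <- which(!ant)
  p_syn <- min(1, r[3L] / max(1e-12, 1 - mean(ant)))
  xor_t1 <- NA_real_
  if (config$nonlinear) {
    # Synergy = (f2 > t2) XOR (f1 > xor_t1); with P(f1 > xor_t1) = 0.1
    # the XOR mass is p2 + 0.1 - 0.2 * p2, solved for the target share
    p_b <- 0.1
    xor_t1 <- threshold_for_share(true_x[rest, f1], 1 - p_b)
    p_b <- mean(true_x[rest, f1] > xor_t1)
    p_a <- min(0.98, max(0.02, (p_syn - p_b) / (1 - 2 * p_b)))
    t2 <- threshold_for_share(true_x[rest, f2], 1 - p_a)
    syn <- xor(true_x[rest, f2] > t2, true_x[rest, f1] > xor_t1)
  } else {
    t2 <- threshold_for_share(true_x[rest, f2], 1 - p_syn)
    syn <- true_x[rest, f2] > t2
  }
  labels[rest[syn]] <- 3L

  shares <- tabulate(labels, nbins = 3L) / n
  if (any(abs(shares - r) > 0.1) || any(shares == 0)) {
    stop("planted rule infeasible for the requested ratios ",
         "(realized shares ", paste(round(shares, 3), collapse = "/"), ")")
  }

  X <- true_x + config$noise_sd * matrix(rnorm(n * v), n, v)
  mins <- apply(X, 2L, min); maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  rng[rng <= 0] <- Inf
  Xs <- sweep(sweep(X, 2L, mins, "-"), 2L, rng, "/")

  ds <- labeled_dataset(
    Xs, class_names[labels],
    drug_pairs = cbind(drug_ids[pairs[, 1L]], drug_ids[pairs[, 2L]]),
    class_names = class_names
  )
  attr(ds, "ground_truth") <- list(
    informative = informative,
    rule_features = unique(c(f1, f2)),
    t1_scaled = (t1 - mins[f1]) / (maxs[f1] - mins[f1]),
    t2_scaled = (t2 - mins[f2]) / (maxs[f2] - mins[f2]),
    xor_t1_scaled = if (config$nonlinear)
                      (xor_t1 - mins[f1]) / (maxs[f1] - mins[f1])
                    else NA_real_,
    t1 = t1, t2 = t2, nonlinear = config$nonlinear,
    scale_min = mins, scale_max = maxs
  )
  ds
}

#' Predict with the planted (Bayes-optimal at zero noise) rule
#'
#' Applies the generator's ground-truth decision list to a dataset's
#' scaled features; with \code{noise_sd = 0} this reproduces the labels
#' exactly, a self-consistency check of the generator.
#'
#' @param ds a dataset produced by \code{\link{generate_synthetic}} (or
#'   any dataset on the same scaled axes).
#' @param truth the \code{"ground_truth"} attribute (taken from \code{ds}
#'   when omitted).
#' @return Character class labels.
#' @export
planted_rule_predict <- function(ds, truth = attr(ds, "ground_truth")) {
  if (is.null(truth)) stop("no ground truth available")
  f1 <- truth$rule_features[1L]
  f2 <- truth$rule_features[length(truth$rule_features)]
  x1 <- ds$features[, f1]
  x2 <- ds$features[, f2]
  out <- rep("Additive", nrow(ds$features))
  ant <- x1 <= truth$t1_scaled
  out[ant] <- "Antagonism"
  if (truth$nonlinear) {
    syn <- !ant & xor(x2 > truth$t2_scaled, x1 > truth$xor_t1_scaled)
  } else {
    syn <- !ant & x2 > truth$t2_scaled
  }
  out[syn] <- "Synergy"
  out
}
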