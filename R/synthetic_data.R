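#' Specification of a synthetic microarray dataset
#'
#' Describes a samples-by-genes simulation mimicking the benchmark regime of
#' public tumor microarray studies: tens to a few hundred samples, thousands
#' of genes, 2-5 diagnostic classes, a small planted set of informative
#' genes, redundant copies of those genes, class imbalance, and a sprinkling
#' of missing intensities. Defaults mirror the small end of that regime
#' (60 samples, 2,000 genes, 2 classes).
#'
#' @param N sample count.
#' @param n gene count.
#' @param m class count.
#' @param n_informative number of genes with class-dependent means.
#' @param n_redundant number of genes that are copies of informative genes
#'   plus `Normal(0, noise_sd)` noise (exact copies by default).
#' @param effect class separation of informative genes, in units of the
#'   within-class standard deviation (which is 1).
#' @param noise_sd standard deviation of the noise added to redundant
#'   copies; 0 plants exact duplicates.
#' @param missing_rate fraction of cells blanked to `NA`, in `[0, 1)`.
#' @param class_probs class prior probabilities (length `m`, summing to 1);
#'   uniform by default.
#' @param seed optional integer seed; the dataset is fully determined by it.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(N = 60, n = 2000, m = 2, n_informative = 10,
                           n_redundant = 5, effect = 2, noise_sd = 0,
                           missing_rate = 0.01, class_probs = NULL,
                           seed = NULL) {
  if (is.null(class_probs)) class_probs <- rep(1 / m, m)
  if (length(class_probs) != m || abs(sum(class_probs) - 1) > 1e-8) {
    rb_stop("class_probs must have length m and sum to 1", "rb_invalid_spec")
  }
  if (n_informative + n_redundant > n) {
    rb_stop("n_informative + n_redundant exceeds the gene count", "rb_invalid_spec")
  }
  if (n_redundant > 0 && n_informative == 0) {
    rb_stop("redundant genes need informative genes to copy", "rb_invalid_spec")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    rb_stop("missing_rate must lie in [0, 1)", "rb_invalid_spec")
  }
  if (m < 2) rb_stop("need at least 2 classes", "rb_invalid_spec")
  if (N < max(2, m)) rb_stop("need at least max(2, m) samples", "rb_invalid_spec")
  structure(list(N = N, n = n, m = m, n_informative = n_informative,
                 n_redundant = n_redundant, effect = effect,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 class_probs = class_probs, seed = seed),
            class = "SyntheticSpec")
}

#' Preset simulation shapes modeled on common benchmark datasets
#'
#' `"colon-like"` (62 samples, 2,000 genes, 2 classes), `"cns-like"` (60,
#' 7,129, 2), `"srbct-like"` (83, 2,308, 4), and `"lung-like"` (181, 12,533,
#' 5) match the shape regimes of widely used public tumor microarray
#' benchmarks.
#'
#' @param preset one of `"colon-like"`, `"cns-like"`, `"srbct-like"`,
#'   `"lung-like"`.
#' @param ... overrides passed to [synthetic_spec()] (e.g. `seed`).
#' @return A `SyntheticSpec`.
#' @export
synthetic_preset <- function(preset = c("colon-like", "cns-like", "srbct-like",
                                        "lung-like"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "colon-like" = list(N = 62, n = 2000, m = 2),
    "cns-like"   = list(N = 60, n = 7129, m = 2),
    "srbct-like" = list(N = 83, n = 2308, m = 4),
    "lung-like"  = list(N = 181, n = 12533, m = 5))
  do.call(synthetic_spec, utils::modifyList(base, list(...)))
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Samples class labels from the spec's priors (redrawing until every class
#' is present), fills the matrix with standard normal noise, and plants:
#'
#' * **informative genes**: gene `g` in class `c` is
#'   `Normal(effect/2 * delta_gc, 1)` where the `delta_gc` are +/-1 patterns
#'   derived from the binary code of the class index, cycling over the code
#'   bits across genes, so that every pair of classes is separated by
#'   `effect` within-class standard deviations on some informative gene;
#' * **redundant genes**: each is a copy of an informative gene (always one
#'   with a smaller column index, so that deterministic tie-breaking in
#'   selection resolves to the original) plus `Normal(0, noise_sd)` noise;
#' * **missing cells**: blanked uniformly at `missing_rate`, never blanking
#'   a whole gene.
#'
#' @param spec a [synthetic_spec()] or [synthetic_preset()].
#' @return List with `dataset` (an [expression_dataset()]), `informative`
#'   and `redundant` (planted column indices), and `redundant_source` (the
#'   informative column each redundant gene copies).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  maybe_set_seed(spec$seed)
  m <- spec$m
  for (try in 1:100) {
    cls <- sample.int(m, spec$N, replace = TRUE, prob = spec$class_probs)
    if (length(unique(cls)) == m) break
    if (try == 100) rb_stop("could not draw all classes; increase N", "rb_invalid_spec")
  }
  v <- matrix(rnorm(spec$N * spec$n), spec$N, spec$n)

  planted <- sort(sample.int(spec$n, spec$n_informative + spec$n_redundant))
  informative <- head(planted, spec$n_informative)
  redundant <- setdiff(planted, informative)
  src <- integer(0)

  if (spec$n_informative > 0) {
    nbits <- max(1L, ceiling(log2(m)))
    for (gi in seq_along(informative)) {
      bit <- (gi - 1L) %% nbits
      delta <- ifelse(bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, bit)) == 0L, 1, -1)
      # means at +/- effect/2 so differing classes are `effect` sd units apart
      v[, informative[gi]] <- rnorm(spec$N, mean = spec$effect / 2 * delta[cls], sd = 1)
    }
  }
  if (spec$n_redundant > 0) {
    src <- sapply(redundant, function(col) {
      cands <- informative[informative < col]
      if (length(cands) == 0) cands <- informative
      cands[sample.int(length(cands), 1)]
    })
    for (k in seq_along(redundant)) {
      v[, redundant[k]] <- v[, src[k]] + rnorm(spec$N, 0, spec$noise_sd)
    }
  }
  if (spec$missing_rate > 0) {
    blank <- which(runif(length(v)) < spec$missing_rate)
    v[blank] <- NA
    # never blank a whole gene
    dead <- which(colSums(!is.na(v)) == 0)
    for (j in dead) v[sample.int(spec$N, 1), j] <- rnorm(1)
  }
  ds <- expression_dataset(v, labels = paste0("class", cls))
  list(dataset = ds, informative = informative, redundant = redundant,
       redundant_source = src)
}
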