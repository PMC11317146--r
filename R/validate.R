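# Self-validation: classification accuracy of the generator -> analyzer
# round trip under rigid motions and coordinate noise.

.random_rotation_rng <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Taxonomy-suite classification accuracy
#'
#' Builds one exemplar per geometry class (WC, aWC, cWH, (w)cWH,
#' non-canonical WC), then applies `n_seeds` independent random rigid
#' motions plus isotropic Gaussian coordinate noise to each and re-runs
#' detection and classification.  Returns the per-class and overall
#' fraction of correctly recovered labels.
#'
#' @param n_seeds replicates per class.
#' @param noise_sd coordinate noise, Angstrom.
#' @param seed master seed; all rotations, translations and noise derive
#'   from it.
#' @return list with `per_class` (named accuracy fractions), `overall`
#'   and `n` (total classified cases).
#' @export
classification_accuracy <- function(n_seeds = 100, noise_sd = 0.05,
                                    seed = 1L) {
  specs <- list(
    WC = pair_spec(geometry = "WC"),
    aWC = pair_spec(geometry = "aWC"),
    cWH = pair_spec(pyr = "5CM", geometry = "cWH"),
    `(w)cWH` = pair_spec(pyr = "5CM", geometry = "(w)cWH"),
    nonWC = pair_spec(geometry = "nonWC"))
  exemplars <- lapply(specs, build_pair)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  noise_seeds <- sample.int(.Machine$integer.max - 1, n_seeds)
  correct <- setNames(integer(length(specs)), names(specs))
  for (k in seq_len(n_seeds)) {
    R <- .random_rotation_rng()
    tr <- stats::runif(3, -20, 20)
    for (nm in names(specs)) {
      m <- rigid_transform(exemplars[[nm]], R, tr)
      if (noise_sd > 0) m <- perturb(m, noise_sd, seed = noise_seeds[k])
      pairs <- detect_base_pairs(m)
      if (length(pairs) == 1 && pairs[[1]]$label == nm)
        correct[nm] <- correct[nm] + 1L
    }
  }
  list(per_class = correct / n_seeds,
       overall = sum(correct) / (n_seeds * length(specs)),
       n = n_seeds * length(specs))
}
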