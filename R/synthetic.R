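# Synthetic labeled datasets with the statistical shape of the real inputs:
# 166 binary fingerprint-like bits plus 13 continuous descriptor-like values
# in [0, 1], with class-dependent distributions and a tunable separation, so
# that the whole pipeline is testable without the (request-only) assay data.

#' Specification of a synthetic dataset
#'
#' Defaults mirror the composition of the reference hERG training corpus
#' (2,389 compounds, 1,004 blockers, i.e. a positive fraction of about
#' 0.42). \code{separation} is a class-separability effect size: informative
#' bits flip their Bernoulli rate by \eqn{\pm separation/4} (clipped so
#' rates stay in (0, 1)) and informative descriptors shift their Gaussian
#' class means by \eqn{\pm separation/2} at unit variance.
#'
#' @param n_samples Number of molecules to generate (>= 2).
#' @param positive_fraction Fraction of blockers (default 1004/2389).
#' @param separation Effect size >= 0; 0 means no class signal.
#' @param n_informative_bits How many of the 166 bits carry signal
#'   (default 40; the first positions of the bit block).
#' @param n_informative_descriptors How many of the 13 descriptors carry
#'   signal (default 6; the first positions of the descriptor block).
#' @param seed Integer seed.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 2389L,
                           positive_fraction = 1004 / 2389,
                           separation = 3,
                           n_informative_bits = 40L,
                           n_informative_descriptors = 6L,
                           seed = 1L) {
  stopifnot(n_samples >= 2, positive_fraction > 0, positive_fraction < 1,
            separation >= 0, n_informative_bits >= 0,
            n_informative_bits <= 166, n_informative_descriptors >= 0,
            n_informative_descriptors <= 13)
  structure(list(n_samples = as.integer(n_samples),
                 positive_fraction = positive_fraction,
                 separation = separation,
                 n_informative_bits = as.integer(n_informative_bits),
                 n_informative_descriptors =
                   as.integer(n_informative_descriptors),
                 seed = as.integer(seed)), class = "synthetic_spec")
}

#' Generate a synthetic labeled dataset
#'
#' Informative bits are Bernoulli with class rates \eqn{0.5 \mp \delta}
#' (nonblocker) and \eqn{0.5 \pm \delta} (blocker) where
#' \eqn{\delta = \min(separation/4, 0.45)}; uninformative bits are
#' Bernoulli(0.3) in both classes. Informative descriptors are Gaussian with
#' class means \eqn{\mp separation/2} at unit variance and are then min-max
#' scaled over the generated column; uninformative descriptors are
#' Uniform(0, 1). The number of positives is the rounded target count.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return List with \code{features} (matrix \code{n x 179}, all values in
#'   \eqn{[0, 1]}, columns \code{f001..f179}, rownames synthetic ids),
#'   \code{labels} (0/1), and \code{spec}.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  n_pos <- round(n * spec$positive_fraction)
  n_pos <- max(1L, min(n - 1L, n_pos))
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  delta <- min(spec$separation / 4, 0.45)
  bits <- matrix(0L, n, 166)
  for (b in seq_len(166)) {
    if (b <= spec$n_informative_bits) {
      p <- ifelse(labels == 1L, 0.5 + delta, 0.5 - delta)
    } else {
      p <- rep(0.3, n)
    }
    bits[, b] <- stats::rbinom(n, 1L, p)
  }
  desc <- matrix(0, n, 13)
  for (d in seq_len(13)) {
    if (d <= spec$n_informative_descriptors) {
      mu <- ifelse(labels == 1L, spec$separation / 2, -spec$separation / 2)
      v <- stats::rnorm(n, mean = mu, sd = 1)
      rng <- range(v)
      desc[, d] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
    } else {
      desc[, d] <- stats::runif(n)
    }
  }
  features <- cbind(bits, desc)
  colnames(features) <- feature_names()
  rownames(features) <- sprintf("synth%05d", seq_len(n))
  list(features = features, labels = labels, spec = spec)
}

#' Small fixture of drug-like SMILES
#'
#' Twenty hard-coded, valid, drug-like molecules with arbitrary 0/1 labels,
#' used to exercise the featurization pipeline end-to-end. The labels are
#' synthetic and carry no pharmacological meaning.
#'
#' @return Data frame with columns \code{id}, \code{smiles}, \code{label}.
#' @export
toy_smiles_fixture <- function() {
  data.frame(
    id = sprintf("toy%02d", 1:20),
    smiles = c(
      "CC(=O)Oc1ccccc1C(=O)O",                      # aspirin
      "CC(C)Cc1ccc(cc1)C(C)C(=O)O",                 # ibuprofen
      "CC(=O)Nc1ccc(O)cc1",                         # paracetamol
      "CN1C=NC2=C1C(=O)N(C(=O)N2C)C",               # caffeine
      "CN1CCC[C@H]1c1cccnc1",                       # nicotine
      "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",              # salbutamol
      "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",           # chlorpromazine
      "COc1ccc2cc(ccc2c1)C(C)C(=O)O",               # naproxen
      "OC(=O)c1ccccc1O",                            # salicylic acid
      "NCCc1ccc(O)c(O)c1",                          # dopamine
      "CC(N)Cc1ccccc1",                             # amphetamine
      "OC(=O)CC(O)(CC(=O)O)C(=O)O",                 # citric acid
      "Nc1ncnc2[nH]cnc12",                          # adenine
      "CCN(CC)CCNC(=O)c1ccc(N)cc1",                 # procainamide
      "CSCCC(N)C(=O)O",                             # methionine
      "NC(Cc1c[nH]c2ccccc12)C(=O)O",                # tryptophan
      "O=S(=O)(N)c1ccc(N)cc1",                      # sulfanilamide
      "CC(C)NCC(O)COc1cccc2ccccc12",                # propranolol
      "OCC(O)C(O)C(O)C(O)CO",                       # sorbitol
      "FC(F)(F)c1ccccc1"),                          # benzotrifluoride
    label = rep(c(1L, 0L), 10),
    stringsAsFactors = FALSE)
}
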