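# Molecular characterization: 166 MACCS fingerprint bits plus 13
# physicochemical descriptors, concatenated into a 179-component feature
# vector and min-max scaled with parameters fitted on the training set.
#
# Fingerprints and most descriptors come from Open Babel (via ChemmineOB);
# ring perception uses ChemmineR. Two descriptors that commercial tools
# compute with proprietary algorithms are replaced by documented open
# approximations: logD at pH 7.4 by a Henderson-Hasselbalch correction of
# Crippen logP, and logS by the ESOL estimate. The molecular surface area is
# an additive atomic-contribution approximation (Labute-style), with
# coefficients frozen in .msa_coefs.

#' Names of the 13 physicochemical descriptors, in their fixed order
#' @export
descriptor_names <- function() c(
  "logP", "logD74", "logS", "MW", "HBD", "HBA", "RotB",
  "Rings", "AromRings", "NplusO", "PSA", "FracPSA", "MSA")

#' Column names of the 179-component feature vector
#' @export
feature_names <- function() sprintf("f%03d", 1:179)

# Per-element contributions (A^2) of the approximate molecular surface
# area, an additive Labute-style accessible-surface model.
.msa_coefs <- c(C = 5.5992, H = 0.4722, N = 5.0841, O = 4.8946, S = 10.4872,
                F = 5.0102, Cl = 11.4152, Br = 15.4669, I = 20.9854,
                P = 8.1535)

# SMARTS patterns used by the descriptor block.
.smarts <- list(
  rotatable = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  aromatic_atom = "[a]",
  heavy_atom = "[!#1]",
  carboxylic_acid = "[CX3](=O)[OX2H1,OX1-]",
  basic_amine = "[NX3;H2,H1,H0;!$(NC=O);!$(N=*);!$([N]~[!#6;!#1]);!a]")

# Parse a molecular formula such as "C9H8O4" into a named element count.
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- c()
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", tk)))
    if (is.na(n)) n <- 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

# Parse one SMILES with Open Babel; stop with the record id on failure.
ob_parse <- function(smiles, id = "?") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop(sprintf("record '%s': empty or invalid SMILES input", id))
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e)
      stop(sprintf("record '%s': SMILES could not be parsed: %s",
                   id, conditionMessage(e)), call. = FALSE))
  mol
}

#' MACCS fingerprint (166 bits)
#'
#' Computes the 166 MACCS structural keys of a molecule with Open Babel's
#' SMARTS definitions. Deterministic for a given SMILES.
#'
#' @param smiles One SMILES string.
#' @param id Record identifier used in error messages.
#' @return Integer vector of 166 zeros/ones.
#' @export
compute_maccs <- function(smiles, id = smiles) {
  mol <- ob_parse(smiles, id)
  fp <- ChemmineOB::fingerprint_OB(mol, "MACCS")
  bits <- as.integer(fp[seq_len(166)])
  stopifnot(length(bits) == 166L, all(bits %in% c(0L, 1L)))
  bits
}

#' The 13 physicochemical descriptors
#'
#' Computes, in fixed order: Crippen logP; logD at pH 7.4 (logP with a
#' Henderson-Hasselbalch ionization correction of -3.4 for carboxylic acids
#' and -2.6 for basic aliphatic amines); logS by the ESOL model; molecular
#' weight (Da); hydrogen-bond donor and acceptor counts; rotatable bonds;
#' ring and aromatic-ring counts (smallest set of smallest rings);
#' nitrogen-plus-oxygen atom count; topological polar surface area
#' (\eqn{\mbox{\AA}^2}); fractional PSA (PSA / molecular surface area,
#' clipped to [0, 1]); and the approximate molecular surface area
#' (\eqn{\mbox{\AA}^2}, additive atomic contributions).
#'
#' @param smiles One SMILES string.
#' @param id Record identifier used in error messages.
#' @return Named numeric vector of length 13 (names =
#'   \code{\link{descriptor_names}}).
#' @export
compute_descriptors <- function(smiles, id = smiles) {
  mol <- ob_parse(smiles, id)
  pr <- ChemmineOB::prop_OB(mol)
  cnt_smarts <- function(s)
    as.numeric(ChemmineOB::smartsSearch_OB(mol, s, uniqueMatches = TRUE))
  elem <- parse_formula(pr$formula)
  known <- intersect(names(elem), names(.msa_coefs))
  msa <- sum(.msa_coefs[known] * elem[known])
  heavy <- cnt_smarts(.smarts$heavy_atom)
  arom <- cnt_smarts(.smarts$aromatic_atom)
  rotb <- cnt_smarts(.smarts$rotatable)
  logp <- pr$logP
  logd <- logp -
    3.4 * (cnt_smarts(.smarts$carboxylic_acid) > 0) -
    2.6 * (cnt_smarts(.smarts$basic_amine) > 0)
  # ESOL: logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RotB - 0.74 AP
  ap <- if (heavy > 0) arom / heavy else 0
  logs <- 0.16 - 0.63 * logp - 0.0062 * pr$MW + 0.066 * rotb - 0.74 * ap
  rng <- ring_counts(smiles, id)
  nplus_o <- sum(elem[intersect(c("N", "O"), names(elem))])
  frac_psa <- if (msa > 0) min(1, max(0, pr$TPSA / msa)) else 0
  out <- c(logP = logp, logD74 = logd, logS = logs, MW = pr$MW,
           HBD = pr$HBD, HBA = pr$HBA1, RotB = rotb,
           Rings = rng[["rings"]], AromRings = rng[["aromatic"]],
           NplusO = as.numeric(nplus_o), PSA = pr$TPSA,
           FracPSA = frac_psa, MSA = msa)
  stopifnot(length(out) == 13L)
  out
}

# SSSR ring count and aromatic ring count via ChemmineR's ring perception.
ring_counts <- function(smiles, id = smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e)
                    stop(sprintf("record '%s': SMILES could not be parsed",
                                 id), call. = FALSE))
  r <- tryCatch(
    unlist(ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = TRUE)),
    error = function(e) c(RINGS = 0, AROMATIC = 0))
  c(rings = as.numeric(r[["RINGS"]]), aromatic = as.numeric(r[["AROMATIC"]]))
}

#' Assemble the 179-component raw feature vector
#'
#' Concatenates the 166 fingerprint bits and the 13 descriptors in their
#' fixed order.
#'
#' @param fp Integer vector of 166 bits.
#' @param desc Numeric vector of 13 descriptors.
#' @return Numeric vector of length 179, named \code{f001..f179}.
#' @export
assemble_features <- function(fp, desc) {
  if (length(fp) != 166L) stop("fingerprint must have exactly 166 bits")
  if (!all(fp %in% c(0, 1))) stop("fingerprint bits must be 0 or 1")
  if (length(desc) != 13L) stop("descriptor block must have exactly 13 values")
  stats::setNames(c(as.numeric(fp), as.numeric(desc)), feature_names())
}

#' Featurize a set of molecules
#'
#' Converts SMILES records to raw 179-component feature vectors.
#' Unparseable records are rejected (not fatal) and reported.
#'
#' @param records Data frame with columns \code{id}, \code{smiles}, and
#'   optionally \code{label} (0/1).
#' @return List with \code{features} (matrix, one row per accepted record,
#'   rownames = ids), \code{labels} (vector or NULL), and \code{rejected}
#'   (data.frame of id and reason).
#' @export
featurize_molecules <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  has_label <- "label" %in% names(records)
  if (has_label) {
    ok_lab <- records$label %in% c(0, 1) | is.na(records$label)
    if (!all(ok_lab)) stop("labels must be exactly 0 or 1")
  }
  rows <- list(); labs <- integer(0); ids <- character(0)
  rej <- data.frame(id = character(), reason = character())
  for (r in seq_len(nrow(records))) {
    id <- as.character(records$id[r])
    v <- tryCatch({
      fp <- compute_maccs(records$smiles[r], id)
      de <- compute_descriptors(records$smiles[r], id)
      assemble_features(fp, de)
    }, error = function(e) e)
    if (inherits(v, "error")) {
      rej <- rbind(rej, data.frame(id = id, reason = conditionMessage(v)))
    } else {
      rows[[length(rows) + 1L]] <- v
      ids <- c(ids, id)
      if (has_label) labs <- c(labs, as.integer(records$label[r]))
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, 179, dimnames = list(NULL, feature_names()))
  rownames(features) <- ids
  list(features = features,
       labels = if (has_label) labs else NULL,
       rejected = rej)
}

#' Fit min-max scaling parameters on a training feature matrix
#'
#' @param x Matrix of raw feature vectors (training rows only).
#' @return A list of class \code{scaling_params} with per-feature
#'   \code{min}, \code{max}, and \code{fitted_on} (row count).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("cannot fit a scaler on an empty matrix")
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max),
                 fitted_on = nrow(x)), class = "scaling_params")
}

#' Apply min-max scaling
#'
#' Componentwise \eqn{x^* = (x - min) / (max - min)}. Features that were
#' constant on the training set map to 0; values outside the training range
#' (possible on unseen data) are clipped to \eqn{[0, 1]}.
#'
#' @param params A \code{\link{fit_scaler}} result.
#' @param x Feature vector or matrix.
#' @return Scaled object of the same shape, all values in \eqn{[0, 1]}.
#' @export
apply_scaler <- function(params, x) {
  stopifnot(inherits(params, "scaling_params"))
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(params$min))
    stop("feature count does not match the fitted scaler")
  rng <- params$max - params$min
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(x, 2L, params$min), 2L, rng, "/")
  out[, const] <- 0
  out <- pmin(pmax(out, 0), 1)   # matrix first so dims survive
  if (vec) drop(out) else out
}

#' Write scaling parameters to a plain-text file
#'
#' Tab-separated columns feature/min/max with the training row count in a
#' header comment.
#'
#' @param params A \code{scaling_params} object.
#' @param path Output path.
#' @export
write_scaler <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# hergcaps scaler  fitted_on=%d\n", params$fitted_on),
      file = con)
  utils::write.table(
    data.frame(feature = names(params$min) %||% feature_names(),
               min = params$min, max = params$max),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read scaling parameters written by \code{\link{write_scaler}}
#'
#' @param path Input path.
#' @return A \code{scaling_params} object.
#' @export
read_scaler <- function(path) {
  first <- readLines(path, n = 1L)
  fitted_on <- as.integer(sub(".*fitted_on=([0-9]+).*", "\\1", first))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(min = stats::setNames(tab$min, tab$feature),
                 max = stats::setNames(tab$max, tab$feature),
                 fitted_on = fitted_on), class = "scaling_params")
}

#' Read a molecule CSV (id, smiles, optional label)
#'
#' @param path CSV path with header \code{id,smiles[,label]}.
#' @return Data frame with character id/smiles and integer label when
#'   present.
#' @export
read_molecules <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(tab)))
    stop("molecule CSV must have columns 'id' and 'smiles'")
  tab$id <- as.character(tab$id)
  if ("label" %in% names(tab)) {
    if (!all(tab$label %in% c(0, 1)))
      stop("labels must be exactly 0 or 1")
    tab$label <- as.integer(tab$label)
  }
  tab
}

#' Write a feature matrix CSV (id + f001..f179 [+ label])
#'
#' @param features Feature matrix with ids as rownames.
#' @param path Output path.
#' @param labels Optional label vector.
#' @export
write_features <- function(features, path, labels = NULL) {
  df <- data.frame(id = rownames(features) %||% seq_len(nrow(features)),
                   features, check.names = FALSE)
  colnames(df) <- c("id", feature_names())
  if (!is.null(labels)) df$label <- as.integer(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a feature CSV written by \code{\link{write_features}}
#'
#' @param path Input path.
#' @return List with \code{features} (matrix) and \code{labels} (or NULL).
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fn <- feature_names()
  if (!all(fn %in% names(tab)))
    stop("feature CSV must contain columns f001..f179")
  features <- as.matrix(tab[, fn])
  rownames(features) <- as.character(tab$id)
  labels <- if ("label" %in% names(tab)) as.integer(tab$label) else NULL
  list(features = features, labels = labels)
}
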