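#' 2D fingerprint from a SMILES string
#'
#' Computes the atom-pair 2D descriptor set of a molecule via ChemmineR
#' (`smiles2sdf()` then `sdf2ap()`), the same toolchain commonly used for
#' Tanimoto screening of drug panels.  The fingerprint is the set of
#' distinct atom-pair descriptor keys, so it is deterministic and
#' independent of the SMILES writing (canonical and non-canonical forms of
#' a molecule give identical sets).  Scheme version: `chemminer-ap-1`.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of descriptor keys (sorted, unique) with
#'   attribute `scheme`.
#' @export
fingerprint_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("fingerprint_from_smiles() requires the ChemmineR package")
  }
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, "query"))),
                  error = function(e) NULL)
  ok <- !is.null(sdf) && length(sdf) == 1 &&
    tryCatch(ChemmineR::validSDF(sdf), error = function(e) FALSE)
  if (!ok) abort(paste0("unparseable SMILES: '", smiles, "'"))
  ap <- tryCatch(suppressWarnings(ChemmineR::sdf2ap(sdf)), error = function(e) NULL)
  if (is.null(ap)) abort(paste0("cannot compute atom pairs for SMILES: '", smiles, "'"))
  bits <- sort_c(unique(format(ChemmineR::ap(ap[[1]]), scientific = FALSE, trim = TRUE)))
  if (length(bits) == 0) abort(paste0("empty fingerprint for SMILES: '", smiles, "'"))
  attr(bits, "scheme") <- "chemminer-ap-1"
  bits
}

#' Tanimoto (Jaccard) coefficient of two fingerprints
#'
#' @param a,b Fingerprints: vectors of bit/descriptor identifiers.
#' @return `|a n b| / |a u b|`, in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) abort("empty fingerprint")
  length(intersect(a, b)) / length(union(a, b))
}

#' Group drugs by structural similarity
#'
#' Builds the graph whose edges connect drug pairs with Tanimoto
#' coefficient strictly above `threshold` and returns its connected
#' components.  Components may chain: two drugs in a group need not
#' themselves be similar, only linked through intermediates.  Singletons
#' are allowed; the result is invariant to input order.
#'
#' @param fingerprints Named list mapping drug id to a fingerprint.
#' @param threshold Similarity cutoff (default 0.35, the conventional
#'   2D-descriptor cutoff for "structurally similar" drugs).
#' @return Tibble `drug_id`, `group` (ids `SG1`, `SG2`, ... ordered by the
#'   lexicographically first member), plus a `pairs` attribute with all
#'   pairwise similarities.
#' @export
structure_groups <- function(fingerprints, threshold = 0.35) {
  ids <- sort_c(names(fingerprints))
  if (length(ids) == 0) {
    return(tibble::tibble(drug_id = character(), group = character()))
  }
  pairs <- if (length(ids) >= 2) {
    cmb <- combn(ids, 2)
    tibble::tibble(
      drug_a = cmb[1, ], drug_b = cmb[2, ],
      tanimoto = vapply(seq_len(ncol(cmb)), function(j) {
        tanimoto(fingerprints[[cmb[1, j]]], fingerprints[[cmb[2, j]]])
      }, numeric(1))
    )
  } else tibble::tibble(drug_a = character(), drug_b = character(), tanimoto = double())
  edges <- pairs[pairs$tanimoto > threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("drug_a", "drug_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  # stable group ids: order components by their first member
  first <- vapply(split(names(comp), comp), function(m) sort_c(m)[1], character(1))
  relabel <- setNames(paste0("SG", seq_along(first)), names(first)[order(first, method = "radix")])
  out <- tibble::tibble(drug_id = ids,
                        group = unname(relabel[as.character(comp[ids])]))
  attr(out, "pairs") <- pairs
  attr(out, "threshold") <- threshold
  out
}
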