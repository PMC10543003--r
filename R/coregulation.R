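#' Complex member coverage
#'
#' For every annotated complex, the fraction of members present in the
#' detected protein set.
#'
#' @param catalog a [ComplexCatalog].
#' @param detected character vector of detected protein ids.
#' @return list with `perComplex` (data.frame: `complex`, `size`,
#'   `nDetected`, `fraction`), `fractionWithDetection` (share of complexes
#'   with at least one detected member) and `meanFraction` (mean
#'   within-complex detected fraction).
#' @export
complexCoverage <- function(catalog, detected) {
  stopIfNot(is(catalog, "ComplexCatalog"), "catalog must be a ComplexCatalog")
  detected <- unique(detected)
  cx <- complexMembers(catalog)
  per <- data.frame(
    complex = names(cx),
    size = vapply(cx, function(m) length(unique(m)), integer(1)),
    nDetected = vapply(cx, function(m)
      length(intersect(unique(m), detected)), integer(1)))
  per$fraction <- per$nDetected / per$size
  rownames(per) <- NULL
  list(perComplex = per,
       fractionWithDetection = mean(per$nDetected >= 1),
       meanFraction = mean(per$fraction))
}

# logical interacting-pair mask over the proteins of a correlation matrix
interactingMask <- function(ids, catalog) {
  mask <- matrix(FALSE, length(ids), length(ids),
                 dimnames = list(ids, ids))
  for (members in complexMembers(catalog)) {
    m <- intersect(unique(members), ids)
    if (length(m) >= 2) mask[m, m] <- TRUE
  }
  diag(mask) <- FALSE
  mask
}

#' Split protein-pair correlations into interacting vs non-interacting
#'
#' Pairs co-occurring in at least one catalog complex are "interacting";
#' every other pair with a defined correlation is "non-interacting" (the
#' two groups partition the defined pairs). Pairs with undefined r are
#' excluded from both groups and counted separately. A one-sided Wilcoxon
#' rank-sum test asks whether interacting pairs are more correlated; the
#' source analysis only contrasts the two densities, so the test is an
#' addition of this implementation.
#'
#' @param corr a [CorrelationMatrix] over proteins (see
#'   [proteinCorrelation()]).
#' @param catalog a [ComplexCatalog].
#' @return list with `interacting` and `nonInteracting` (numeric r
#'   vectors), `nUndefined`, and `stats` (`medianInteracting`,
#'   `medianNonInteracting`, `meanInteracting`, `meanNonInteracting`, `W`,
#'   `p` of the one-sided rank-sum test).
#' @export
pairCorrelationSplit <- function(corr, catalog) {
  stopIfNot(is(corr, "CorrelationMatrix"), "corr must be a CorrelationMatrix")
  r <- corValues(corr)
  ids <- rownames(r)
  mask <- interactingMask(ids, catalog)
  ut <- upper.tri(r)
  defined <- !is.na(r) & ut
  ri <- r[defined & mask]
  rn <- r[defined & !mask]
  if (!length(ri))
    stop("no defined pairs in the interacting group", call. = FALSE)
  if (!length(rn))
    stop("no defined pairs in the non-interacting group", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(ri, rn, alternative = "greater",
                                     exact = FALSE))
  list(interacting = ri, nonInteracting = rn,
       nUndefined = sum(ut & is.na(r)),
       stats = list(medianInteracting = median(ri),
                    medianNonInteracting = median(rn),
                    meanInteracting = mean(ri),
                    meanNonInteracting = mean(rn),
                    W = unname(wt$statistic), p = wt$p.value))
}

#' Per-compartment correlation distributions
#'
#' For each subcellular compartment, the distribution of pairwise Pearson
#' correlations over all detected proteins annotated there. A protein
#' localized to several compartments contributes to every one of them.
#' Compartments with fewer than two detected proteins are skipped with a
#' warning.
#'
#' @param corr a [CorrelationMatrix] over proteins.
#' @param locmap a [LocalizationMap].
#' @return list with `summary` (data.frame: `compartment`, `nProteins`,
#'   `nPairs`, `median`, `mean`) and `rValues` (named list of r vectors).
#' @export
compartmentCorrelation <- function(corr, locmap) {
  stopIfNot(is(corr, "CorrelationMatrix"), "corr must be a CorrelationMatrix")
  stopIfNot(is(locmap, "LocalizationMap"), "locmap must be a LocalizationMap")
  r <- corValues(corr)
  ids <- rownames(r)
  loc <- proteinLocations(locmap)
  long <- data.frame(protein = rep(names(loc), lengths(loc)),
                     compartment = unlist(loc, use.names = FALSE))
  long <- long[long$protein %in% ids, , drop = FALSE]
  comps <- unique(long$compartment)
  rvals <- list()
  rows <- list()
  for (cc in comps) {
    members <- unique(long$protein[long$compartment == cc])
    if (length(members) < 2) {
      warning("compartment '", cc, "' has fewer than 2 detected proteins; ",
              "skipped")
      next
    }
    sub <- r[members, members, drop = FALSE]
    v <- sub[upper.tri(sub)]
    v <- v[!is.na(v)]
    rvals[[cc]] <- v
    rows[[cc]] <- data.frame(compartment = cc, nProteins = length(members),
                             nPairs = length(v),
                             median = if (length(v)) median(v) else NA_real_,
                             mean = if (length(v)) mean(v) else NA_real_)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compartment = character(0), nProteins = integer(0),
               nPairs = integer(0), median = numeric(0), mean = numeric(0))
  rownames(summary) <- NULL
  list(summary = summary, rValues = rvals)
}

#' Read a complex catalog
#'
#' GMT input (one complex per line) or a two-column TSV (`complex_id`,
#' `member`). Binary interaction lists are naturally represented as
#' two-member complexes.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`.
#' @return A [ComplexCatalog].
#' @export
readComplexCatalog <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "gmt") return(ComplexCatalog(readGmt(path)))
  tab <- read.delim(path, colClasses = "character")
  stopIfNot(all(c("complex_id", "member") %in% colnames(tab)),
            "TSV needs columns complex_id, member")
  ComplexCatalog(split(tab$member, tab$complex_id))
}

#' Read a localization map
#'
#' @param path two-column TSV (`protein`, `compartment`); proteins may
#'   appear on several lines, one per compartment.
#' @return A [LocalizationMap].
#' @export
readLocalizationMap <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  stopIfNot(all(c("protein", "compartment") %in% colnames(tab)),
            "TSV needs columns protein, compartment")
  LocalizationMap(lapply(split(tab$compartment, tab$protein), unique))
}
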