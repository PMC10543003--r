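#' Differential reaction perturbation score (DRPS)
#'
#' For each entity linked to a reaction, the span of its row-mean-normalized
#' log2 abundance is the maximum absolute difference between any two
#' samples (equivalently max minus min over non-missing values). The DRPS
#' is the largest span over the reaction's measured entities, and 0 when no
#' entity is measured or no sample pair exists.
#'
#' @param entityValues numeric matrix (entities x samples) or vector (one
#'   entity) of row-mean-normalized log2 abundances.
#' @return Non-negative DRPS in log2-abundance units.
#' @export
reactionDrps <- function(entityValues) {
  if (is.null(entityValues)) return(0)
  if (!is.matrix(entityValues))
    entityValues <- matrix(entityValues, nrow = 1)
  if (nrow(entityValues) == 0 || ncol(entityValues) == 0) return(0)
  spans <- apply(entityValues, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else max(v) - min(v)
  })
  if (!length(spans)) 0 else max(spans)
}

# DRPS for every reaction of one pathway entry against a value matrix
pathwayReactionScores <- function(reactions, values) {
  vapply(reactions, function(ents) {
    ents <- intersect(ents, rownames(values))
    if (!length(ents)) return(0)
    reactionDrps(values[ents, , drop = FALSE])
  }, numeric(1))
}

#' Differential pathway perturbation score (DPPS)
#'
#' The root-mean-square of the reaction scores: squared DRPS values are
#' summed, divided by the total number of reactions in the pathway
#' (including reactions without measured entities, which score 0), and the
#' square root is taken. A single-reaction pathway with one entity reduces
#' to that entity's abundance span.
#'
#' @param model a [PathwayModel].
#' @param pathway pathway identifier in `model`.
#' @param values numeric matrix of row-mean-normalized log2 abundances
#'   (entities x samples), or an [AbundanceExperiment].
#' @return Non-negative DPPS; 0 iff every reaction's DRPS is 0.
#' @export
pathwayDpps <- function(model, pathway, values) {
  if (is(values, "AbundanceExperiment")) values <- abundanceValues(values)
  reactions <- pathwayReactions(model, pathway)
  stopIfNot(length(reactions) >= 1, "pathway must have at least one reaction")
  drps <- pathwayReactionScores(reactions, values)
  sqrt(sum(drps^2) / length(reactions))
}

#' Rank pathways by perturbation score
#'
#' @param model a [PathwayModel].
#' @param values entities-x-samples matrix of row-mean-normalized log2
#'   abundances, or an [AbundanceExperiment].
#' @param topN report the top `topN` pathways (default all).
#' @return data.frame sorted by DPPS descending (ties broken alphabetically
#'   by pathway id) with columns `pathway`, `name`, `dpps`, `rank`,
#'   `nReactions`, `nEntities`, `nMeasured`, `coverage` (measured fraction
#'   of the pathway's entities).
#' @export
rankPathways <- function(model, values, topN = Inf) {
  if (is(values, "AbundanceExperiment")) values <- abundanceValues(values)
  ids <- pathwayIds(model)
  rows <- lapply(ids, function(id) {
    reactions <- pathwayReactions(model, id)
    ents <- unique(unlist(reactions, use.names = FALSE))
    measured <- intersect(ents, rownames(values))
    data.frame(pathway = id, name = model@pathways[[id]]$name,
               dpps = pathwayDpps(model, id, values),
               nReactions = length(reactions),
               nEntities = length(ents), nMeasured = length(measured),
               coverage = if (length(ents)) length(measured) / length(ents)
                          else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$dpps, out$pathway), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  head(out[, c("pathway", "name", "dpps", "rank", "nReactions", "nEntities",
               "nMeasured", "coverage")], n = topN)
}

#' Re-rank pathways after removing entities
#'
#' Masks a set of entities from the abundance matrix, recomputes every
#' DPPS, and reports the rank shift per pathway. This is the in-silico
#' knockout used to ask which pathway scores are carried by a few driver
#' enzymes: a pathway whose perturbation rests on the removed entities
#' falls down the ranking.
#'
#' @inheritParams rankPathways
#' @param removedEntities character vector of entity ids to mask; must be
#'   present in `values`. An empty set returns an identity re-ranking.
#' @return data.frame with columns `pathway`, `name`, `dppsBefore`,
#'   `rankBefore`, `dppsAfter`, `rankAfter`, `rankShift`
#'   (`rankAfter - rankBefore`).
#' @export
leaveOutRerank <- function(model, values, removedEntities) {
  if (is(values, "AbundanceExperiment")) values <- abundanceValues(values)
  removedEntities <- unique(removedEntities)
  missing <- setdiff(removedEntities, rownames(values))
  stopIfNot(length(missing) == 0,
            paste0("entities not in the matrix: ",
                   paste(missing, collapse = ", ")))
  before <- rankPathways(model, values)
  after <- rankPathways(model,
                        values[setdiff(rownames(values), removedEntities), ,
                               drop = FALSE])
  m <- merge(before[, c("pathway", "name", "dpps", "rank")],
             after[, c("pathway", "dpps", "rank")],
             by = "pathway", suffixes = c("Before", "After"))
  names(m) <- c("pathway", "name", "dppsBefore", "rankBefore", "dppsAfter",
                "rankAfter")
  m$rankShift <- m$rankAfter - m$rankBefore
  m[order(m$rankBefore), , drop = FALSE]
}

#' Read a pathway model
#'
#' JSON layout: `{pathway_id: {"name": ..., "reactions": {reaction_id:
#' [entity ids]}}}`. The TSV layout is a flat three-column table
#' `pathway_id`, `reaction_id`, `entity_id` (empty entity ids give
#' entity-less reactions).
#'
#' @param path file path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return A [PathwayModel].
#' @importFrom jsonlite fromJSON
#' @importFrom utils read.delim head write.table
#' @export
readPathwayModel <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- fromJSON(path, simplifyVector = FALSE)
    pw <- lapply(raw, function(p)
      list(name = as.character(p$name %||% ""),
           reactions = lapply(p$reactions, function(e)
             as.character(unlist(e, use.names = FALSE)))))
    return(PathwayModel(pw))
  }
  tab <- read.delim(path, colClasses = "character")
  stopIfNot(all(c("pathway_id", "reaction_id", "entity_id") %in%
                  colnames(tab)),
            "TSV needs columns pathway_id, reaction_id, entity_id")
  pw <- lapply(split(tab, tab$pathway_id), function(d) {
    reactions <- lapply(split(d$entity_id, d$reaction_id), function(e)
      e[nzchar(e)])
    list(name = d$pathway_id[1], reactions = reactions)
  })
  PathwayModel(pw)
}

#' Write a pathway model as JSON
#'
#' @param model a [PathwayModel].
#' @param path output file.
#' @return `path`, invisibly.
#' @importFrom jsonlite write_json
#' @export
writePathwayModel <- function(model, path) {
  write_json(model@pathways, path, auto_unbox = TRUE)
  invisible(path)
}
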