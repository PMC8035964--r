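#' OR-consensus of several prediction sets
#'
#' Decision-level fusion: the consensus label set of a protein is the union
#' (element-wise logical OR) of the member models' predicted sets, so a
#' location is called whenever *any* member calls it.  The consensus set is by
#' construction a superset of every member's set, which can only raise
#' per-instance recall -- the property that makes the fusion attractive for
#' recovering multi-compartment proteins that single Label Powerset models
#' tend to collapse to one site.  Consensus scores, needed only for ranking
#' metrics, are the element-wise maximum of the member scores.
#'
#' @param members List of at least two [`scl_prediction`][predict.scl_lp]
#'   objects sharing id order and universe.
#' @return An `scl_prediction` object.
#' @examples
#' # two single-location calls fuse into a dual-location consensus
#' a <- sclconsensus:::new_scl_prediction(
#'   "P1", c("C", "I", "O", "P", "S", "V"),
#'   matrix(c(0L, 0L, 0L, 0L, 1L, 0L), 1), matrix(c(0, 0, 0, 0, 1, 0), 1))
#' b <- sclconsensus:::new_scl_prediction(
#'   "P1", c("C", "I", "O", "P", "S", "V"),
#'   matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 1), matrix(c(1, 0, 0, 0, 0, 0), 1))
#' consensus_or(list(a, b))$predicted
#' @export
consensus_or <- function(members) {
  if (length(members) < 2) abort("consensus needs at least two member predictions")
  ref <- members[[1]]
  for (m in members[-1]) {
    if (!identical(m$ids, ref$ids)) abort("consensus members disagree on protein id order")
    if (!identical(m$universe, ref$universe)) abort("consensus members disagree on label universe")
  }
  predicted <- Reduce(`|`, lapply(members, function(m) m$predicted == 1L))
  scores <- Reduce(pmax, lapply(members, function(m) m$scores))
  new_scl_prediction(ref$ids, ref$universe, predicted + 0L, scores,
                     model = paste0("consensus(",
                                    paste(vapply(members, function(m) m$model,
                                                 character(1)), collapse = " | "),
                                    ")"))
}
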