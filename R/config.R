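#' Read agent and opponent specifications from a config file
#'
#' The config file is YAML with two optional top-level maps, `agents` and
#' `opponents`, one named block per specification. Agent blocks take the
#' [agent_spec()] fields (`kind`, `order`, `params`, `seed`); opponent blocks
#' take the [opponent_spec()] fields (`algorithm`, `max_order`, `alpha`,
#' `min_count`, `deterministic_counter`, `seed`). Markov-table agents list
#' their policy under `params: {variables: [...], table: {context: p, ...}}`.
#'
#' @param path Path to the YAML config file.
#' @return List with elements `agents` (named list of `agent_spec`) and
#'   `opponents` (named list of `opponent_spec`).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "agents:",
#'   "  subject: {kind: wsls, seed: 1}",
#'   "opponents:",
#'   "  exploiter: {algorithm: 2, alpha: 0.05}"), cfg)
#' read_specs(cfg)
#' @export
read_specs <- function(path) {
  cfg <- yaml::read_yaml(path)
  agents <- lapply(cfg$agents %||% list(), .meta_to_agent)
  opponents <- lapply(cfg$opponents %||% list(), .meta_to_opponent)
  list(agents = agents, opponents = opponents)
}
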