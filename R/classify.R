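#' Load outcome classification rules
#'
#' Outcome rules map response output transitions to cellular outcome labels
#' (survival, apoptosis, necroptosis) and give an ordered list of resolution
#' rules for pathways that reach several responses at once. Rules live in a
#' declarative YAML file, not in code, so a model's classification scheme can
#' be adjusted without touching the package. Format:
#'
#' ```yaml
#' response_outputs:
#'   Apoptosis: apoptosis
#'   Necroptosis: necroptosis
#'   Survival: survival
#' resolution_rules:
#'   - label: apoptosis
#'     requires_outputs: [apoptosis]
#'     requires_transitions: [T_bcl2_bax]
#' ```
#'
#' @param path YAML file; defaults to the rules shipped for the bundled
#'   TNFR1-architecture model
#' @param net optional `petri_net`; when given, every referenced transition is
#'   checked to exist
#' @return list of class `outcome_rules`
#' @export
read_outcome_rules <- function(path = NULL, net = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tnfr1_synthetic", "outcome_rules.yaml",
                        package = "pnpath", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  rules <- list(
    response_outputs = unlist(raw$response_outputs),
    resolution_rules = lapply(raw$resolution_rules, function(r)
      list(label = r$label,
           requires_outputs = as.character(r$requires_outputs %||% character(0)),
           requires_transitions = as.character(r$requires_transitions %||% character(0))))
  )
  if (!is.null(net)) {
    refs <- c(names(rules$response_outputs),
              unlist(lapply(rules$resolution_rules, `[[`, "requires_transitions")))
    unknown <- setdiff(refs, net$transitions$id)
    if (length(unknown)) .stopf("outcome rules reference unknown transitions: %s",
                                paste(unknown, collapse = ", "))
  }
  structure(rules, class = "outcome_rules")
}

#' Classify one Manatee invariant by its cellular outcome
#'
#' The response output transitions present in the MI's Parikh support decide
#' the label: exactly one response output gives its outcome directly; several
#' responses are resolved by the first matching resolution rule and otherwise
#' labelled "ambiguous"; an MI reaching no response output is "housekeeping"
#' (pure turnover such as synthesis plus degradation of a transcription
#' factor). For summary pie-chart counting, housekeeping is grouped with
#' ambiguous as "not classified to a unique response".
#'
#' @param mi a `manatee_invariant`
#' @param rules an `outcome_rules` object
#' @return label: one of the rule labels, "ambiguous", or "housekeeping"
#' @export
classify_mi <- function(mi, rules) {
  sup <- names(mi$parikh)
  hits <- intersect(names(rules$response_outputs), sup)
  labels <- unique(unname(rules$response_outputs[hits]))
  if (length(labels) == 0L) return("housekeeping")
  if (length(labels) == 1L) return(labels)
  for (r in rules$resolution_rules) {
    if (all(r$requires_outputs %in% labels) &&
        all(r$requires_transitions %in% sup)) {
      return(r$label)
    }
  }
  "ambiguous"
}

#' Classify a list of MIs and tabulate outcomes
#'
#' @param mis list of MIs
#' @param rules an `outcome_rules` object
#' @return list with `labels` (per MI), `counts` (per outcome label),
#'   `n_classified` (MIs with a unique outcome), and `n_ambiguous`
#'   (ambiguous plus housekeeping, the MIs excluded from the outcome chart)
#' @export
classify_mis <- function(mis, rules) {
  labels <- vapply(mis, classify_mi, character(1), rules = rules)
  outcome_levels <- unique(unname(rules$response_outputs))
  counts <- vapply(outcome_levels, function(l) sum(labels == l), numeric(1))
  list(labels = labels,
       counts = counts,
       n_classified = sum(labels %in% outcome_levels),
       n_ambiguous = sum(!(labels %in% outcome_levels)))
}

#' Write a TSV classification summary
#'
#' One row per outcome category plus ambiguous/housekeeping, matching the
#' categories of an outcome pie chart.
#'
#' @param classification result of [classify_mis()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_classification_tsv <- function(classification, path) {
  tab <- table(classification$labels)
  df <- data.frame(outcome = names(tab), n_mis = as.integer(tab))
  utils::write.table(df[order(df$outcome), ], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
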