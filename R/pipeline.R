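#' Run the full invariant / pathway / knockout / clustering pipeline
#'
#' End-to-end analysis of a Petri net: place and transition invariants with
#' coverage diagnostics, Manatee invariants with classification of TIs and
#' outcome labels for MIs, the in-silico knockout matrix with protein
#' ranking, and the UPGMA cluster tree of knockout profiles. Stage outputs
#' are written under `out_dir` (JSON/TSV/CSV/Newick) together with a
#' machine-readable `summary.json` holding every headline count. All stages
#' are deterministic; inconclusive realizability checks are reported in the
#' summary, never hidden.
#'
#' @param model a `petri_net`, a path to a PNML/SBML file, or `"tnfr1"` for
#'   the bundled model
#' @param out_dir output directory (created); NULL to skip writing files
#' @param stages character subset of
#'   `c("invariants", "manatee", "classify", "knockout", "cluster")`
#' @param rules an `outcome_rules` object or YAML path (defaults to the
#'   bundled rules when the bundled model is analysed)
#' @param experiments knockout experiments (default: model-defined or all
#'   input transitions)
#' @param max_coeff,budget Manatee search parameters (see
#'   [manatee_invariants()])
#' @return list with all stage results and `summary`
#' @export
run_pipeline <- function(model = "tnfr1", out_dir = NULL,
                         stages = c("invariants", "manatee", "classify",
                                    "knockout", "cluster"),
                         rules = NULL, experiments = NULL,
                         max_coeff = 3, budget = 1e6) {
  stages <- match.arg(stages, several.ok = TRUE)
  manifest <- NULL
  if (inherits(model, "petri_net")) {
    net <- model
  } else if (identical(model, "tnfr1")) {
    loaded <- load_tnfr1()
    net <- loaded$net
    manifest <- loaded$manifest
    if (is.null(experiments)) experiments <- tnfr1_experiments(net, manifest)
    if (is.null(rules)) rules <- read_outcome_rules(net = net)
  } else if (grepl("\\.pnml$", model, ignore.case = TRUE)) {
    net <- read_pnml(model)
  } else {
    net <- read_sbml(model)
  }
  if (is.character(rules)) rules <- read_outcome_rules(rules, net = net)

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(out_dir, ...)
  res <- list(net = net, manifest = manifest)
  summary <- list(places = nrow(net$places),
                  transitions = nrow(net$transitions),
                  edges = n_edges(net),
                  tokens = sum(net$marking))

  need_inv <- any(c("invariants", "manatee", "classify", "knockout",
                    "cluster") %in% stages)
  if (need_inv) {
    res$pis <- place_invariants(net)
    res$tis <- transition_invariants(net)
    res$coverage <- coverage(net, res$tis, res$pis)
    summary$n_place_invariants <- length(res$pis)
    summary$n_transition_invariants <- length(res$tis)
    summary$is_CTI <- res$coverage$is_CTI
    summary$is_CPI <- res$coverage$is_CPI
    if (!is.null(out_dir) && "invariants" %in% stages) {
      write_invariants(res$tis, out("transition_invariants.json"))
      write_invariants(res$tis, out("transition_invariants.tsv"))
      write_invariants(res$pis, out("place_invariants.json"))
      write_incidence_csv(net, out("incidence_matrix.csv"))
    }
  }

  need_mi <- any(c("manatee", "classify", "knockout", "cluster") %in% stages)
  if (need_mi) {
    mi_res <- manatee_invariants(net, res$tis, max_coeff = max_coeff,
                                 budget = budget)
    res$mis <- mi_res$mis
    res$inconclusive <- mi_res$inconclusive
    res$ti_classes <- classify_tis(net, res$tis, res$mis)
    summary$n_manatee_invariants <- length(res$mis)
    summary$n_inconclusive_combinations <- length(mi_res$inconclusive)
    summary$n_singleton_mis <- sum(vapply(res$mis, function(m)
      length(m$ti_coefficients) == 1L && m$ti_coefficients[[1]] == 1,
      logical(1)))
    summary$n_complete_tis <- sum(res$ti_classes %in% c("complete", "trivial"))
    summary$n_trivial_tis <- sum(res$ti_classes == "trivial")
    summary$n_dissected_tis <- sum(res$ti_classes == "dissected")
    if (!is.null(out_dir) && "manatee" %in% stages) {
      write_manatee_json(res$mis, out("manatee_invariants.json"))
    }
  }

  if ("classify" %in% stages && !is.null(rules)) {
    res$classification <- classify_mis(res$mis, rules)
    for (i in seq_along(res$mis)) {
      res$mis[[i]]$outcome <- res$classification$labels[[i]]
    }
    summary$outcome_counts <- as.list(res$classification$counts)
    summary$n_classified_mis <- res$classification$n_classified
    summary$n_ambiguous_mis <- res$classification$n_ambiguous
    if (!is.null(out_dir)) {
      write_classification_tsv(res$classification, out("classification.tsv"))
    }
  }

  if (any(c("knockout", "cluster") %in% stages)) {
    res$knockout <- knockout_matrix(net, res$mis, experiments = experiments)
    res$ranking <- rank_proteins(res$knockout)
    summary$knockout_rows <- nrow(res$knockout$affected)
    summary$knockout_cols <- ncol(res$knockout$affected)
    summary$top_ranked <- res$ranking$experiment[1]
    if (!is.null(out_dir) && "knockout" %in% stages) {
      write_knockout_matrix(res$knockout, out("knockout_matrix.csv"))
      write_knockout_matrix(res$knockout, out("knockout_long.tsv"), "long")
      utils::write.table(res$ranking, out("protein_ranking.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }

  if ("cluster" %in% stages) {
    D <- pearson_distance_matrix(res$knockout$affected)
    res$tree <- upgma(D)
    summary$tree_root_height <- max(res$tree$height)
    if (!is.null(out_dir)) {
      write_distance_tsv(D, out("knockout_distances.tsv"))
      write_newick(res$tree, out("knockout_tree.nwk"))
    }
  }

  res$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  res
}
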