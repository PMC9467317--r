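#' Define a knockout experiment
#'
#' A knockout deletes one or more synthesis (input) transitions, emulating the
#' loss of a protein. By default only input transitions (and transitions
#' explicitly allowed via `allow_any`) may be knocked.
#'
#' @param net a `petri_net`
#' @param knocked character vector of transition ids to delete
#' @param name experiment label (defaults to the knocked ids joined by "+")
#' @param allow_any permit knocking non-input transitions (e.g. translations
#'   of gene-regulated proteins, which consume an mRNA place)
#' @return object of class `knockout_experiment`
#' @export
knockout_experiment <- function(net, knocked, name = NULL, allow_any = FALSE) {
  unknown <- setdiff(knocked, net$transitions$id)
  if (length(unknown)) .stopf("unknown transition id: %s",
                              paste(unknown, collapse = ", "))
  if (!allow_any) {
    kinds <- net$transitions$kind[match(knocked, net$transitions$id)]
    bad <- knocked[kinds != "input"]
    if (length(bad)) .stopf("not input (synthesis) transitions: %s (use allow_any = TRUE)",
                            paste(bad, collapse = ", "))
  }
  structure(list(name = name %||% paste(knocked, collapse = "+"),
                 knocked = sort(unique(knocked), method = "radix")),
            class = "knockout_experiment")
}

#' Places affected by a knockout
#'
#' An MI survives a knockout iff its Parikh support contains none of the
#' knocked transitions. A place is *affected* iff it lies in no surviving
#' MI-induced subnetwork, among the places that lie in at least one MI-induced
#' subnetwork overall. Places never covered by any MI are reported separately
#' by [knockout_diagnostics()] rather than counted as trivially affected.
#'
#' @param net a `petri_net`
#' @param mis list of MIs from [manatee_invariants()]
#' @param experiment a `knockout_experiment` (or character vector of ids)
#' @param downstream_only restrict the affected set to places forward
#'   reachable from the knocked transitions (compatibility with
#'   path-restricted knockout semantics); default FALSE, the global
#'   MI-coverage rule
#' @return character vector of affected place ids
#' @export
knockout_affected <- function(net, mis, experiment, downstream_only = FALSE) {
  if (is.character(experiment)) {
    experiment <- knockout_experiment(net, experiment, allow_any = TRUE)
  }
  covered <- .sort_ids(unique(unlist(lapply(mis, `[[`, "places"))))
  surviving <- .surviving_mis(mis, experiment$knocked)
  alive <- .sort_ids(unique(unlist(lapply(mis[surviving], `[[`, "places"))))
  affected <- setdiff(covered, alive)
  if (downstream_only) {
    affected <- intersect(affected, .reachable_places(net, experiment$knocked))
  }
  affected
}

# Forward reachability (places) from a set of transitions over the arc list.
.reachable_places <- function(net, transitions) {
  frontier <- transitions
  seen_t <- character(0)
  places <- character(0)
  while (length(frontier)) {
    seen_t <- union(seen_t, frontier)
    prod <- net$arcs$target[net$arcs$source %in% frontier &
                              net$arcs$target %in% net$places$id]
    new_p <- setdiff(prod, places)
    places <- union(places, new_p)
    nxt <- net$arcs$target[net$arcs$source %in% new_p]
    frontier <- setdiff(intersect(nxt, net$transitions$id), seen_t)
  }
  .sort_ids(places)
}

.surviving_mis <- function(mis, knocked) {
  vapply(mis, function(mi) !any(knocked %in% names(mi$parikh)), logical(1))
}

#' Build the in-silico knockout matrix
#'
#' Applies [knockout_affected()] row-wise. Default experiments are all input
#' (synthesis) transitions; default columns are all places that belong to no
#' place invariant (PI places are conserved and can never be knocked out by
#' removing a synthesis) and are covered by at least one MI.
#'
#' @param net a `petri_net`
#' @param mis list of MIs
#' @param experiments list of `knockout_experiment`s; NULL for one single
#'   knockout per input transition
#' @param columns character vector of column place ids; NULL for the default
#' @return object of class `knockout_matrix`: logical matrix `affected`
#'   (TRUE = affected) with experiment names as rows and place ids as columns,
#'   plus `experiments` and per-row surviving-MI fractions
#' @export
knockout_matrix <- function(net, mis, experiments = NULL, columns = NULL) {
  if (is.null(experiments)) {
    syn <- net$transitions$id[net$transitions$kind == "input"]
    experiments <- lapply(syn, function(t) knockout_experiment(net, t))
  }
  if (length(experiments) == 0L) .stopf("empty experiment list")
  covered <- .sort_ids(unique(unlist(lapply(mis, `[[`, "places"))))
  if (is.null(columns)) {
    pi_places <- unique(unlist(lapply(place_invariants(net), `[[`, "support")))
    columns <- setdiff(covered, pi_places)
  } else {
    unknown <- setdiff(columns, net$places$id)
    if (length(unknown)) .stopf("unknown column places: %s",
                                paste(unknown, collapse = ", "))
  }
  columns <- sort(columns, method = "radix")
  nm <- vapply(experiments, `[[`, character(1), "name")
  aff <- matrix(FALSE, length(experiments), length(columns),
                dimnames = list(nm, columns))
  frac_mi <- numeric(length(experiments))
  for (i in seq_along(experiments)) {
    a <- knockout_affected(net, mis, experiments[[i]])
    aff[i, ] <- columns %in% a
    frac_mi[i] <- 1 - sum(.surviving_mis(mis, experiments[[i]]$knocked)) / length(mis)
  }
  structure(list(affected = aff, experiments = experiments,
                 affected_mi_fraction = stats::setNames(frac_mi, nm)),
            class = "knockout_matrix")
}

#' @export
print.knockout_matrix <- function(x, ...) {
  cat(sprintf("<knockout_matrix> %d experiments x %d places, %.1f%% affected entries\n",
              nrow(x$affected), ncol(x$affected), 100 * mean(x$affected)))
  invisible(x)
}

#' Knockout diagnostics
#'
#' Lists places excluded from the default column set: PI places (conserved)
#' and places covered by no MI-induced subnetwork (these would be trivially
#' affected in every row).
#'
#' @param net a `petri_net`
#' @param mis list of MIs
#' @return list with `pi_places` and `uncovered_places`
#' @export
knockout_diagnostics <- function(net, mis) {
  covered <- unique(unlist(lapply(mis, `[[`, "places")))
  pi_places <- unique(unlist(lapply(place_invariants(net), `[[`, "support")))
  list(pi_places = .sort_ids(pi_places),
       uncovered_places = .sort_ids(setdiff(net$places$id, covered)))
}

#' Named multi-knockout presets
#'
#' Drug-mimicking multiple knockouts for the bundled TNFR1-architecture model:
#' `"smac_mimetic"` (IAP inhibition: knockout of XIAP and cIAP1/2 synthesis)
#' and `"cycloheximide"` (translation blockade of the five NF-kB-upregulated
#' genes: IkB, A20, XIAP, cFLIP_L, BCL-2).
#'
#' @param net a `petri_net` containing the preset's transitions
#' @param name preset name
#' @return a `knockout_experiment`
#' @export
multiple_knockout_preset <- function(net, name) {
  presets <- list(
    smac_mimetic = c("trans_XIAP", "syn_cIAP"),
    cycloheximide = c("trans_IkB", "trans_A20", "trans_XIAP",
                      "trans_cFLIPL", "trans_BCL2")
  )
  if (!name %in% names(presets)) {
    .stopf("unknown preset '%s'; available: %s", name,
           paste(names(presets), collapse = ", "))
  }
  knockout_experiment(net, presets[[name]], name = name, allow_any = TRUE)
}

#' Rank knocked proteins by knockout impact
#'
#' Two impact metrics per experiment: the fraction of MIs whose pathway is
#' destroyed by the knockout, and the fraction of matrix column places that
#' become affected. The primary sort key is configurable; ties break
#' lexicographically by experiment name.
#'
#' @param km a `knockout_matrix`
#' @param by primary metric, "mi_fraction" (default) or "place_fraction"
#' @return data.frame sorted descending with columns `experiment`,
#'   `mi_fraction`, `place_fraction`
#' @export
rank_proteins <- function(km, by = c("mi_fraction", "place_fraction")) {
  by <- match.arg(by)
  df <- data.frame(
    experiment = rownames(km$affected),
    mi_fraction = unname(km$affected_mi_fraction),
    place_fraction = rowMeans(km$affected)
  )
  key <- if (by == "mi_fraction") df$mi_fraction else df$place_fraction
  df <- df[order(-key, df$experiment, method = "radix"), ]
  rownames(df) <- NULL
  df
}

#' Export a knockout matrix
#'
#' Wide CSV (rows = experiments, columns = places, cells 0/1) or long-format
#' TSV (`experiment`, `place`, `affected`) suitable for heatmap plotting.
#'
#' @param km a `knockout_matrix`
#' @param path output path
#' @param format "wide" (default, CSV) or "long" (TSV)
#' @return `path`, invisibly
#' @export
write_knockout_matrix <- function(km, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(experiment = rownames(km$affected),
                     km$affected * 1L, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    long <- expand.grid(experiment = rownames(km$affected),
                        place = colnames(km$affected),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$affected <- as.integer(km$affected[cbind(long$experiment, long$place)])
    utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
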