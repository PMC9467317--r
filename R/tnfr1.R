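#' Load the bundled TNFR1-architecture Petri net
#'
#' Returns a discrete Place/Transition model of TNFR1-mediated signal
#' transduction: receptor complex I assembly with K63/M1 ubiquitination,
#' NF-kB activation with IkB feedback and five NF-kB-dependent gene-expression
#' modules (IkB, A20, XIAP, cFLIP_L, BCL-2 — the five conserved gene motifs
#' carrying the initial tokens), complex IIa/IIb formation with caspase-8
#' activation, extrinsic and intrinsic (mitochondrial) apoptosis, and the
#' RIP1/RIP3/MLKL necroptosis branch. The system is open: 26 housekeeping
#' protein syntheses plus 5 gene-dependent translations feed it, and
#' degradation, dissociation, and the three cellular response outputs
#' (Survival, Apoptosis, Necroptosis) drain it.
#'
#' This model is a *synthetic reconstruction*: it was assembled from published
#' structural descriptions of TNFR1 signalling (component lists, complex
#' compositions, knockout dependencies), not transcribed from any specific
#' supplementary file, and it is bundled for reproducible, download-free
#' analysis. Structural headline figures — 118 places, 130 transitions, 299
#' edges, five place invariants of support two, 31 synthesis transitions —
#' hold by construction and are verified against the manifest at load time.
#'
#' @param check verify manifest counts at load time (default TRUE)
#' @return list with `net` (a `petri_net`) and `manifest`
#' @export
load_tnfr1 <- function(check = TRUE) {
  dir <- system.file("extdata", "tnfr1_synthetic", package = "pnpath",
                     mustWork = TRUE)
  places <- utils::read.delim(file.path(dir, "places.tsv"))
  transitions <- utils::read.delim(file.path(dir, "transitions.tsv"))
  arcs <- utils::read.delim(file.path(dir, "arcs.tsv"))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  marking <- stats::setNames(places$marking, places$id)
  net <- petri_net(places[, c("id", "name", "annotation")],
                   transitions, arcs, marking = marking[marking > 0])
  if (check) {
    ec <- manifest$expected_counts
    checks <- c(places = nrow(net$places), transitions = nrow(net$transitions),
                edges = n_edges(net))
    want <- c(places = ec$places, transitions = ec$transitions, edges = ec$edges)
    bad <- names(checks)[checks != want]
    if (length(bad)) {
      .stopf("model integrity error: %s",
             paste(sprintf("%s is %d, manifest expects %d", bad,
                           checks[bad], want[bad]), collapse = "; "))
    }
    missing_t <- setdiff(unlist(manifest$synthesis_transitions),
                         net$transitions$id)
    if (length(missing_t)) .stopf("manifest names unknown transitions: %s",
                                  paste(missing_t, collapse = ", "))
    if (!setequal(names(which(net$marking > 0)),
                  unlist(manifest$initial_marking_places))) {
      .stopf("model integrity error: initial marking places differ from manifest")
    }
  }
  list(net = net, manifest = manifest)
}

#' Knockout experiment set of the bundled model
#'
#' The 31 knockable synthesis transitions: 26 housekeeping protein syntheses
#' (input transitions) plus the 5 translations of the NF-kB-upregulated genes
#' (internal transitions consuming an mRNA; knockable because they are the
#' only supply of their protein).
#'
#' @param net,manifest from [load_tnfr1()]
#' @return list of `knockout_experiment`s, one per synthesis transition
#' @export
tnfr1_experiments <- function(net, manifest) {
  lapply(unlist(manifest$synthesis_transitions), function(t)
    knockout_experiment(net, t, allow_any = TRUE))
}

#' Validate the bundled model against its manifest
#'
#' Structural diagnostics embodying the invariant-based verification
#' criteria: bipartiteness and count matches, CTI after invariant
#' computation (every reaction takes part in some steady-state flow), and
#' the place-invariant supports against the expected gene-conservation
#' pairs. Failures are listed in the report, not thrown.
#'
#' @param net a `petri_net`
#' @param manifest from [load_tnfr1()]
#' @param tis,pis optional precomputed invariants (computed when NULL)
#' @return list with `ok` and a character vector `failures`
#' @export
validate_model <- function(net, manifest, tis = NULL, pis = NULL) {
  failures <- character(0)
  ec <- manifest$expected_counts
  if (nrow(net$places) != ec$places)
    failures <- c(failures, sprintf("place count %d != %d", nrow(net$places), ec$places))
  if (nrow(net$transitions) != ec$transitions)
    failures <- c(failures, sprintf("transition count %d != %d",
                                    nrow(net$transitions), ec$transitions))
  if (n_edges(net) != ec$edges)
    failures <- c(failures, sprintf("edge count %d != %d", n_edges(net), ec$edges))
  if (is.null(pis)) pis <- place_invariants(net)
  if (is.null(tis)) tis <- transition_invariants(net)
  cov <- coverage(net, tis, pis)
  if (!cov$is_CTI)
    failures <- c(failures, sprintf("net is not CTI; uncovered: %s",
                                    paste(cov$uncovered_transitions, collapse = ", ")))
  want_pi <- lapply(manifest$expected_pi_supports, function(s)
    sort(unlist(s), method = "radix"))
  got_pi <- lapply(pis, `[[`, "support")
  for (w in want_pi) {
    if (!any(vapply(got_pi, identical, logical(1), w))) {
      failures <- c(failures, sprintf("expected PI support missing: %s",
                                      paste(w, collapse = ",")))
    }
  }
  if (length(got_pi) != length(want_pi))
    failures <- c(failures, sprintf("PI count %d != %d", length(got_pi),
                                    length(want_pi)))
  list(ok = length(failures) == 0L, failures = failures,
       coverage = cov, n_tis = length(tis), n_pis = length(pis))
}
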