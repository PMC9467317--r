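#' Incidence matrix of a Petri net
#'
#' The incidence matrix \eqn{C} is the |P| x |T| integer matrix whose entry
#' \eqn{C[p, t] = W(t, p) - W(p, t)} gives the net token change on place p
#' when transition t fires. Read-arc pairs contribute zero: C describes the
#' pure part of the net, so enabling logic must consult the arc list, never C.
#' Rows and columns are ordered deterministically (lexicographic by id).
#'
#' @param net a `petri_net`
#' @return integer matrix with place ids as rownames, transition ids as colnames
#' @export
incidence_matrix <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  net$C
}

#' Write an incidence matrix as CSV
#'
#' Plain CSV with a header row of transition ids and a leading column of
#' place ids, suitable for spreadsheet inspection or external tools.
#'
#' @param net a `petri_net`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_incidence_csv <- function(net, path) {
  C <- incidence_matrix(net)
  df <- data.frame(place = rownames(C), C, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Is a transition enabled?
#'
#' A transition is enabled at marking m iff every pre-place holds at least the
#' arc weight in tokens; places tested by a read arc count as pre-places. An
#' input transition (no pre-places) is always enabled.
#'
#' @param net a `petri_net`
#' @param marking named numeric vector over places (defaults to the initial marking)
#' @param t transition id
#' @return logical
#' @export
is_enabled <- function(net, marking = NULL, t) {
  m <- .as_marking(net, marking)
  j <- match(t, colnames(net$pre))
  if (is.na(j)) .stopf("unknown transition id: %s", t)
  all(m >= net$pre[, j])
}

#' Fire a transition
#'
#' Removes `W(p, t)` tokens from each pre-place and adds `W(t, p)` tokens to
#' each post-place in one timeless step; a place tested via a read arc keeps
#' its token count. Firing a disabled transition is a state error.
#'
#' @inheritParams is_enabled
#' @return the successor marking (named numeric vector)
#' @export
fire <- function(net, marking = NULL, t) {
  m <- .as_marking(net, marking)
  j <- match(t, colnames(net$pre))
  if (is.na(j)) .stopf("unknown transition id: %s", t)
  if (!all(m >= net$pre[, j])) .stopf("transition '%s' is not enabled", t)
  m - net$pre[, j] + net$post[, j]
}

#' Fire a sequence of transitions
#'
#' @inheritParams is_enabled
#' @param sequence character vector of transition ids, fired in order
#' @return the final marking
#' @export
fire_sequence <- function(net, marking = NULL, sequence) {
  m <- .as_marking(net, marking)
  for (t in sequence) m <- fire(net, m, t)
  m
}

#' Transitions enabled at a marking
#'
#' @inheritParams is_enabled
#' @return character vector of enabled transition ids
#' @export
enabled_transitions <- function(net, marking = NULL) {
  m <- .as_marking(net, marking)
  colnames(net$pre)[colSums(net$pre > m) == 0]
}

#' Random firing walk
#'
#' Repeatedly fires a uniformly chosen enabled transition; used for
#' property checks such as place-invariant conservation.
#'
#' @inheritParams is_enabled
#' @param steps maximum number of firings
#' @return list with `markings` (matrix, one row per visited marking) and
#'   `sequence` of fired transition ids
#' @export
random_walk <- function(net, marking = NULL, steps = 100) {
  m <- .as_marking(net, marking)
  seqs <- character(0)
  mk <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  for (i in seq_len(steps)) {
    en <- enabled_transitions(net, m)
    if (length(en) == 0L) break
    t <- en[sample.int(length(en), 1L)]
    m <- fire(net, m, t)
    seqs <- c(seqs, t)
    mk <- rbind(mk, m)
  }
  list(markings = mk, sequence = seqs)
}

.as_marking <- function(net, marking) {
  if (is.null(marking)) return(net$marking)
  ids <- net$places$id
  if (length(marking) == length(ids) && is.null(names(marking))) {
    return(stats::setNames(as.numeric(marking), ids))
  }
  m <- stats::setNames(numeric(length(ids)), ids)
  unknown <- setdiff(names(marking), ids)
  if (length(unknown)) .stopf("marking names unknown places: %s",
                              paste(unknown, collapse = ", "))
  m[names(marking)] <- as.numeric(marking)
  m
}

#' Subnetwork induced by a transition support
#'
#' The invariant-induced subnetwork consists of the given transitions, every
#' place adjacent to one of them (including read-arc neighbours), and all arcs
#' between those vertices. The initial marking is restricted to the retained
#' places.
#'
#' @param net a `petri_net`
#' @param support character vector of transition ids
#' @return a `petri_net` fragment
#' @export
induced_subnetwork <- function(net, support) {
  support <- unique(support)
  unknown <- setdiff(support, net$transitions$id)
  if (length(unknown)) .stopf("unknown transitions in support: %s",
                              paste(unknown, collapse = ", "))
  places <- induced_places(net, support)
  arcs <- net$arcs[(net$arcs$source %in% support & net$arcs$target %in% places) |
                     (net$arcs$source %in% places & net$arcs$target %in% support), ,
                   drop = FALSE]
  petri_net(net$places[net$places$id %in% places, , drop = FALSE],
            net$transitions[net$transitions$id %in% support, c("id", "name"), drop = FALSE],
            arcs,
            marking = net$marking[places])
}

#' Places adjacent to a transition support
#'
#' @inheritParams induced_subnetwork
#' @return character vector of place ids (lexicographic)
#' @export
induced_places <- function(net, support) {
  if (length(support) == 0L) return(character(0))
  j <- match(support, colnames(net$pre))
  if (anyNA(j)) .stopf("unknown transitions in support: %s",
                       paste(support[is.na(j)], collapse = ", "))
  touched <- rowSums(net$pre[, j, drop = FALSE]) + rowSums(net$post[, j, drop = FALSE]) > 0
  sort(rownames(net$pre)[touched], method = "radix")
}
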