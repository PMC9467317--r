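#' Construct a Place/Transition Petri net
#'
#' A P/T net is the quintuple \eqn{N = (P, T, F, W, m_0)}: places (passive
#' entities such as proteins, genes, or complexes), transitions (reactions),
#' weighted directed arcs between vertices of different type, and an initial
#' marking assigning a non-negative token count to every place. The net may be
#' open: transitions without pre-places model syntheses, transitions without
#' post-places model degradation, dissociation, or a cellular response.
#'
#' Read arcs (bidirectional test arcs) are stored as a flagged pair of opposite
#' arcs of equal weight. They take part in enabling and firing (where the two
#' directions cancel) but are excluded from the incidence matrix, which is
#' defined for the pure part of the net only.
#'
#' @param places character vector of place ids, or a data.frame with columns
#'   `id` and optionally `name`, `annotation`, `logical_copy`.
#' @param transitions character vector of transition ids, or a data.frame with
#'   columns `id` and optionally `name`.
#' @param arcs data.frame with columns `source`, `target`, optional `weight`
#'   (default 1) and optional `read` (default FALSE). A read arc may be given
#'   as a single row with the place as `source`; the opposite arc is added
#'   automatically.
#' @param marking named numeric vector of initial token counts; places not
#'   named hold zero tokens. May be NULL for an empty marking.
#'
#' @return An object of class `petri_net` with components `places`,
#'   `transitions`, `arcs`, `marking`, and cached `pre`/`post` weight matrices.
#' @examples
#' net <- petri_net(
#'   places = c("A", "B"),
#'   transitions = c("syn", "conv", "deg"),
#'   arcs = data.frame(
#'     source = c("syn", "A", "conv", "B"),
#'     target = c("A", "conv", "B", "deg")
#'   )
#' )
#' incidence_matrix(net)
#' @export
petri_net <- function(places, transitions, arcs = NULL, marking = NULL) {
  places <- .norm_places(places)
  transitions <- .norm_transitions(transitions)
  if (anyDuplicated(places$id)) .stopf("duplicate place ids")
  if (anyDuplicated(transitions$id)) .stopf("duplicate transition ids")
  if (length(intersect(places$id, transitions$id)) > 0L) {
    .stopf("ids shared between places and transitions: %s",
           paste(intersect(places$id, transitions$id), collapse = ", "))
  }

  places <- places[.id_order(places$id), , drop = FALSE]
  transitions <- transitions[.id_order(transitions$id), , drop = FALSE]
  rownames(places) <- NULL
  rownames(transitions) <- NULL

  arcs <- .norm_arcs(arcs, places$id, transitions$id)

  m <- stats::setNames(numeric(nrow(places)), places$id)
  if (!is.null(marking) && length(marking)) {
    if (is.null(names(marking))) .stopf("marking must be a named vector")
    unknown <- setdiff(names(marking), places$id)
    if (length(unknown)) .stopf("marking names unknown places: %s",
                                paste(unknown, collapse = ", "))
    if (any(marking < 0)) .stopf("marking must be non-negative")
    m[names(marking)] <- as.numeric(marking)
  }

  net <- structure(
    list(places = places, transitions = transitions, arcs = arcs, marking = m),
    class = "petri_net"
  )
  net <- .cache_matrices(net)
  net$transitions$kind <- transition_kinds(net)
  net
}

.norm_places <- function(places) {
  if (is.character(places)) {
    places <- data.frame(id = places, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(places) || is.null(places$id)) {
    .stopf("places must be a character vector or a data.frame with an 'id' column")
  }
  if (is.null(places$name)) places$name <- places$id
  if (is.null(places$annotation)) places$annotation <- NA_character_
  if (is.null(places$logical_copy)) places$logical_copy <- FALSE
  places[, c("id", "name", "annotation", "logical_copy")]
}

.norm_transitions <- function(transitions) {
  if (is.character(transitions)) {
    transitions <- data.frame(id = transitions, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(transitions) || is.null(transitions$id)) {
    .stopf("transitions must be a character vector or a data.frame with an 'id' column")
  }
  if (is.null(transitions$name)) transitions$name <- transitions$id
  transitions[, c("id", "name")]
}

.norm_arcs <- function(arcs, place_ids, transition_ids) {
  if (is.null(arcs) || nrow(as.data.frame(arcs)) == 0L) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), read = logical(),
                      stringsAsFactors = FALSE))
  }
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (is.null(arcs$weight)) arcs$weight <- 1
  if (is.null(arcs$read)) arcs$read <- FALSE
  arcs <- arcs[, c("source", "target", "weight", "read")]
  arcs$weight <- as.numeric(arcs$weight)
  arcs$read <- as.logical(arcs$read)
  if (any(arcs$weight < 1 | arcs$weight != floor(arcs$weight))) {
    .stopf("arc weights must be positive integers")
  }

  src_place <- arcs$source %in% place_ids
  src_trans <- arcs$source %in% transition_ids
  tgt_place <- arcs$target %in% place_ids
  tgt_trans <- arcs$target %in% transition_ids
  bad <- !((src_place & tgt_trans) | (src_trans & tgt_place))
  if (any(bad)) {
    .stopf("arcs must connect a place and a transition (bipartite); offending: %s",
           paste(paste(arcs$source[bad], arcs$target[bad], sep = "->"), collapse = ", "))
  }

  # Expand single-row read arcs into the flagged opposite pair.
  rd <- which(arcs$read)
  if (length(rd)) {
    for (i in rd) {
      j <- which(arcs$read & arcs$source == arcs$target[i] &
                   arcs$target == arcs$source[i])
      if (length(j) == 0L) {
        arcs <- rbind(arcs, data.frame(source = arcs$target[i],
                                       target = arcs$source[i],
                                       weight = arcs$weight[i], read = TRUE))
      } else if (any(arcs$weight[j] != arcs$weight[i])) {
        .stopf("read arc pair %s <-> %s has unequal weights",
               arcs$source[i], arcs$target[i])
      }
    }
  }
  key <- paste(arcs$source, arcs$target, sep = "\r")
  if (anyDuplicated(key)) .stopf("duplicate arcs: %s",
                                 paste(unique(gsub("\r", "->", key[duplicated(key)])), collapse = ", "))
  ord <- order(arcs$source, arcs$target, method = "radix")
  arcs <- arcs[ord, , drop = FALSE]
  rownames(arcs) <- NULL
  arcs
}

.cache_matrices <- function(net) {
  np <- nrow(net$places); nt <- nrow(net$transitions)
  pre <- matrix(0, np, nt, dimnames = list(net$places$id, net$transitions$id))
  post <- pre
  a <- net$arcs
  if (nrow(a)) {
    pt <- a$source %in% net$places$id          # place -> transition rows
    if (any(pt)) {
      idx <- cbind(match(a$source[pt], net$places$id),
                   match(a$target[pt], net$transitions$id))
      pre[idx] <- pre[idx] + a$weight[pt]
    }
    if (any(!pt)) {
      idx <- cbind(match(a$target[!pt], net$places$id),
                   match(a$source[!pt], net$transitions$id))
      post[idx] <- post[idx] + a$weight[!pt]
    }
  }
  net$pre <- pre
  net$post <- post
  # Pure (read-arc-free) part for the incidence matrix.
  prp <- pre; pop <- post
  rd <- a$read
  if (any(rd)) {
    ar <- a[rd, , drop = FALSE]
    pt <- ar$source %in% net$places$id
    if (any(pt)) {
      idx <- cbind(match(ar$source[pt], net$places$id),
                   match(ar$target[pt], net$transitions$id))
      prp[idx] <- prp[idx] - ar$weight[pt]
    }
    if (any(!pt)) {
      idx <- cbind(match(ar$target[!pt], net$places$id),
                   match(ar$source[!pt], net$transitions$id))
      pop[idx] <- pop[idx] - ar$weight[!pt]
    }
  }
  net$pre_pure <- prp
  net$post_pure <- pop
  net$C <- pop - prp
  net
}

#' Classify transitions as input, output, or internal
#'
#' A transition with no incoming arcs is an input (synthesis); one with no
#' outgoing arcs is an output (degradation, dissociation, or a cellular
#' response). Read arcs count in both directions, so a transition touching a
#' place only via a read arc is internal.
#'
#' @param net a `petri_net`
#' @return character vector of kinds, aligned with `net$transitions$id`.
#' @export
transition_kinds <- function(net) {
  has_in <- colSums(net$pre) > 0
  has_out <- colSums(net$post) > 0
  kind <- rep("internal", length(has_in))
  kind[!has_in & has_out] <- "input"
  kind[has_in & !has_out] <- "output"
  kind[!has_in & !has_out] <- "isolated"
  stats::setNames(kind, colnames(net$pre))
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("<petri_net> %d places, %d transitions, %d arcs (%d read), %s tokens\n",
              nrow(x$places), nrow(x$transitions), nrow(x$arcs),
              sum(x$arcs$read), format(sum(x$marking))))
  kinds <- table(x$transitions$kind)
  cat("  transitions:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Number of directed edges of a net
#'
#' Each row of the arc table is one directed edge; a read arc therefore
#' contributes two edges.
#' @param net a `petri_net`
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$arcs)

#' Merge logical place copies
#'
#' Layout tools duplicate a heavily connected place into several "logical"
#' gray copies. In the underlying net these copies are one vertex. This
#' helper rewires all arcs of places sharing a name with a logical copy onto
#' a single place and drops the duplicates.
#'
#' @param net a `petri_net`
#' @param strict error when merged copies carry conflicting annotations
#' @return a `petri_net` with copies merged
#' @export
merge_logical_places <- function(net, strict = FALSE) {
  pl <- net$places
  if (!any(pl$logical_copy)) return(net)
  keep <- !duplicated(pl$name)
  map <- stats::setNames(pl$id[keep][match(pl$name, pl$name[keep])], pl$id)
  if (strict) {
    ann <- split(pl$annotation, pl$name)
    bad <- names(ann)[vapply(ann, function(a) length(unique(a[!is.na(a)])) > 1L, logical(1))]
    if (length(bad)) .stopf("conflicting annotations on logical copies of: %s",
                            paste(bad, collapse = ", "))
  }
  arcs <- net$arcs
  arcs$source <- ifelse(arcs$source %in% names(map), map[arcs$source], arcs$source)
  arcs$target <- ifelse(arcs$target %in% names(map), map[arcs$target], arcs$target)
  key <- paste(arcs$source, arcs$target)
  agg <- stats::aggregate(weight ~ source + target + read, data = arcs, FUN = sum)
  mk <- tapply(net$marking, map[names(net$marking)], sum)
  pl2 <- pl[keep, , drop = FALSE]
  pl2$logical_copy <- FALSE
  petri_net(pl2, net$transitions[, c("id", "name")], agg,
            marking = stats::setNames(as.numeric(mk), names(mk)))
}
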