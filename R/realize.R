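#' Realize a Parikh vector as a firing sequence
#'
#' Searches for an ordered firing sequence in which each transition fires
#' exactly the requested number of times and every step is enabled, starting
#' from `marking`. This decides whether a transition-invariant combination is
#' executable from the initial state, i.e. whether it is a complete pathway
#' rather than a dissected one.
#'
#' The search is depth-first backtracking with memoization on
#' (marking, remaining counts) states. Two exact prunings are applied:
#' input transitions (no pre-places) are fired greedily first, because adding
#' tokens can never disable anything, and a branch is abandoned when some
#' remaining transition needs tokens on a place that neither the marking nor
#' the remaining production can supply. The node budget bounds the search;
#' exhaustion yields an explicit `"inconclusive"` status, never a silent
#' failure, so callers can distinguish "proven unrealizable" from "gave up".
#'
#' @param net a `petri_net`
#' @param marking starting marking (defaults to the net's initial marking)
#' @param counts named non-negative integer vector of firing counts per
#'   transition id; omitted transitions fire zero times
#' @param budget maximum number of search nodes (default 1e6)
#' @return list with `status` ("realized", "unrealizable", or "inconclusive"),
#'   `sequence` (character vector, only for "realized"), and `nodes` visited
#' @examples
#' net <- petri_net(c("A"), c("syn", "deg"),
#'                  data.frame(source = c("syn", "A"), target = c("A", "deg")))
#' realize_parikh(net, counts = c(syn = 1, deg = 1))$sequence
#' @export
realize_parikh <- function(net, marking = NULL, counts, budget = 1e6) {
  m0 <- .as_marking(net, marking)
  tid <- colnames(net$pre)
  cnt <- stats::setNames(numeric(length(tid)), tid)
  if (length(counts)) {
    if (is.null(names(counts))) .stopf("counts must be named by transition id")
    unknown <- setdiff(names(counts), tid)
    if (length(unknown)) .stopf("unknown transition id: %s",
                                paste(unknown, collapse = ", "))
    if (any(counts < 0 | counts != floor(counts))) {
      .stopf("counts must be non-negative integers")
    }
    cnt[names(counts)] <- as.numeric(counts)
  }
  if (sum(cnt) == 0) return(list(status = "realized", sequence = character(0), nodes = 0))

  pre <- net$pre; post <- net$post
  active <- which(cnt > 0)
  pre_a <- pre[, active, drop = FALSE]
  post_a <- post[, active, drop = FALSE]
  # pure production (read arcs excluded): a transition testing a place via a
  # read arc does not supply tokens to it
  postp_a <- net$post_pure[, active, drop = FALSE]
  is_input <- colSums(pre_a) == 0
  is_output <- colSums(post_a) == 0 & !is_input
  rem0 <- cnt[active]

  # Final-marking check: the run must not consume more than it produces on
  # any place. Shortfall places are exactly the missing-token requirements.
  final <- m0 + as.vector((post_a - pre_a) %*% rem0)
  if (any(final < 0)) {
    return(list(status = "unrealizable", sequence = NULL, nodes = 0,
                blocking = sort(names(final)[final < 0], method = "radix"),
                n_firable = 0))
  }

  # Output transitions only remove tokens: any realizable sequence can be
  # rearranged (adjacent swaps stay enabled) so that every output firing
  # forms a suffix, and given the non-negative final marking that suffix is
  # always fireable. Outputs are therefore excluded from the search and
  # appended at the end.
  out_suffix <- rep(colnames(pre_a)[is_output], rem0[is_output])
  rem0[is_output] <- 0
  if (sum(rem0) == 0) {
    return(list(status = "realized", sequence = out_suffix, nodes = 0,
                n_firable = ncol(pre_a)))
  }

  env <- new.env(parent = emptyenv())
  nodes <- 0L
  exhausted <- FALSE
  # restrict memo keys to places the active transitions can touch
  touched <- which(rowSums(pre_a) + rowSums(post_a) > 0)

  # Necessary condition: current tokens plus everything the remaining firings
  # can still produce must cover every remaining transition's demand.
  feasible <- function(m, rem) {
    avail <- m + as.vector(post_a %*% rem)
    !any(pre_a[, rem > 0, drop = FALSE] > avail)
  }

  search <- function(m, rem) {
    if (sum(rem) == 0) return(character(0))
    nodes <<- nodes + 1L
    if (nodes > budget) {
      exhausted <<- TRUE
      return(NULL)
    }
    # Greedy prefix: fire all remaining input transitions (token-monotone).
    prefix <- character(0)
    gr <- is_input & rem > 0
    if (any(gr)) {
      for (j in which(gr)) {
        k <- rem[j]
        prefix <- c(prefix, rep(colnames(pre_a)[j], k))
        m <- m + post_a[, j] * k
        rem[j] <- 0
      }
      if (sum(rem) == 0) return(prefix)
    }
    if (!feasible(m, rem)) return(NULL)
    key <- paste(c(m[touched], rem), collapse = ",")
    if (!is.null(env[[key]])) return(NULL)  # memoized dead state
    cand <- which(rem > 0)
    cand <- cand[colSums(pre_a[, cand, drop = FALSE] > m) == 0]
    for (j in cand) {
      m2 <- m - pre_a[, j] + post_a[, j]
      rem2 <- rem
      rem2[j] <- rem2[j] - 1
      res <- search(m2, rem2)
      if (!is.null(res)) return(c(prefix, colnames(pre_a)[j], res))
      if (exhausted) return(NULL)
    }
    env[[key]] <- TRUE
    NULL
  }

  # Stage 1: sound unrealizability proof. A transition can only ever fire if
  # each pre-place is supplied by the initial marking or by some other
  # transition of the Parikh vector that can itself fire; the fixed point of
  # that relation over-approximates firability, so a required transition
  # outside it proves the vector unrealizable in any order.
  firable <- rep(FALSE, ncol(pre_a))
  repeat {
    supplied <- m0 > 0
    if (any(firable)) {
      supplied <- supplied | rowSums(postp_a[, firable, drop = FALSE]) > 0
    }
    newf <- !firable & colSums(pre_a > 0 & !supplied) == 0
    if (!any(newf)) break
    firable <- firable | newf
  }
  if (!all(firable)) {
    # blocking places: pre-places of never-firable transitions that neither
    # the marking nor any firable transition of the vector supplies — the
    # vector's true external token requirements
    supplied <- m0 > 0
    if (any(firable)) {
      supplied <- supplied | rowSums(postp_a[, firable, drop = FALSE]) > 0
    }
    need <- rowSums(pre_a[, !firable, drop = FALSE] > 0) > 0
    blocking <- sort(rownames(pre_a)[need & !supplied], method = "radix")
    return(list(status = "unrealizable", sequence = NULL, nodes = 0,
                blocking = blocking, n_firable = sum(firable)))
  }

  # Stage 2: greedy maximal firing often completes outright for pathway
  # nets; a few deterministic orderings are tried before falling back to
  # full backtracking.
  n_fir <- ncol(pre_a)
  greedy <- NULL
  for (pick in c("first", "last", "most", "least")) {
    g <- .greedy_fire(m0, pre_a, post_a, rem0, is_input, pick)
    if (is.null(g$stuck)) {
      return(list(status = "realized",
                  sequence = c(g$sequence, out_suffix), nodes = 0,
                  n_firable = n_fir))
    }
    if (is.null(greedy)) greedy <- g
  }

  # Stage 3: full backtracking within the node budget.
  res <- search(m0, rem0)
  if (!is.null(res)) {
    list(status = "realized", sequence = c(res, out_suffix), nodes = nodes,
         n_firable = n_fir)
  } else if (exhausted) {
    list(status = "inconclusive", sequence = NULL, nodes = nodes,
         n_firable = n_fir)
  } else {
    # ordering deadlock: report the places the greedy stuck state is short of
    stuck <- greedy$stuck
    short <- net$pre[, names(stuck)[stuck > 0], drop = FALSE] > greedy$marking
    blocking <- sort(rownames(net$pre)[rowSums(short) > 0], method = "radix")
    list(status = "unrealizable", sequence = NULL, nodes = nodes,
         blocking = blocking, n_firable = n_fir)
  }
}

.greedy_fire <- function(m, pre_a, post_a, rem, is_input, pick = "first") {
  seqs <- character(0)
  repeat {
    if (sum(rem) == 0) return(list(sequence = seqs, stuck = NULL, marking = m))
    gr <- which(is_input & rem > 0)
    if (length(gr)) {
      for (j in gr) {
        seqs <- c(seqs, rep(colnames(pre_a)[j], rem[j]))
        m <- m + post_a[, j] * rem[j]
        rem[j] <- 0
      }
      next
    }
    cand <- which(rem > 0)
    en <- cand[colSums(pre_a[, cand, drop = FALSE] > m) == 0]
    if (length(en) == 0L) return(list(sequence = seqs, stuck = rem, marking = m))
    j <- switch(pick,
                first = en[1L],
                last = en[length(en)],
                most = en[which.max(rem[en])],
                least = en[which.min(rem[en])])
    m <- m - pre_a[, j] + post_a[, j]
    rem[j] <- rem[j] - 1
    seqs <- c(seqs, colnames(pre_a)[j])
  }
}

# Firability fixed point: which transitions of a Parikh vector can ever fire
# from marking m0, over-approximating token supply (read arcs excluded from
# production). Returns a logical vector over the active transitions.
.firable_set <- function(net, m0, counts) {
  active <- names(counts)[counts > 0]
  pre_a <- net$pre[, active, drop = FALSE]
  postp_a <- net$post_pure[, active, drop = FALSE]
  firable <- rep(FALSE, length(active))
  repeat {
    supplied <- m0 > 0
    if (any(firable)) {
      supplied <- supplied | rowSums(postp_a[, firable, drop = FALSE]) > 0
    }
    newf <- !firable & colSums(pre_a > 0 & !supplied) == 0
    if (!any(newf)) break
    firable <- firable | newf
  }
  stats::setNames(firable, active)
}

# Greedy maximal firing of a Parikh vector; returns the stuck state and the
# set of places that block the remaining transitions. Used to pick which
# provider invariants to add during Manatee construction.
.stuck_places <- function(net, marking, counts) {
  m <- .as_marking(net, marking)
  tid <- colnames(net$pre)
  rem <- stats::setNames(numeric(length(tid)), tid)
  rem[names(counts)] <- as.numeric(counts)
  pre <- net$pre; post <- net$post
  repeat {
    cand <- which(rem > 0)
    if (length(cand) == 0L) break
    en <- cand[colSums(pre[, cand, drop = FALSE] > m) == 0]
    if (length(en) == 0L) break
    j <- en[1L]
    m <- m - pre[, j] + post[, j]
    rem[j] <- rem[j] - 1
  }
  cand <- which(rem > 0)
  if (length(cand) == 0L) return(character(0))
  short <- pre[, cand, drop = FALSE] > m
  sort(unique(rownames(pre)[rowSums(short) > 0]), method = "radix")
}
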