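#' Manatee invariants: realizable combinations of transition invariants
#'
#' Most transition invariants of a detailed signalling net are *dissected*
#' pathways: their firing balance holds, but they cannot actually run from the
#' initial marking because they borrow tokens (an assembled complex, a nuclear
#' transcription factor) that some other invariant must produce. A Manatee
#' invariant (MI) is a non-negative integer combination of TIs whose combined
#' Parikh vector is realizable from the initial marking — a complete pathway
#' from receptor activation to cellular response.
#'
#' Construction is breadth-first per seed TI: starting from each single TI,
#' while the combination's Parikh vector is not realizable (via
#' [realize_parikh()]), the greedily stuck state identifies the blocking
#' pre-places and the search branches on every TI whose firing produces such a
#' place. For each seed, only combinations minimal for that seed are kept
#' (no recorded combination for the same seed is componentwise smaller); the
#' final set is deduplicated by Parikh vector. Each MI carries a realizability
#' witness (a full firing sequence returning to the initial marking).
#'
#' During branching, a candidate provider is kept only when its addition
#' actually resolves the requirement branched on (the blocking place leaves
#' the combination's blocking set); providers that cannot fire in context —
#' typically members of the same deadlocked cycle — are discarded, which
#' keeps the frontier to the genuine alternative routes.
#'
#' @param net a `petri_net` with its initial marking
#' @param tis list from [transition_invariants()]
#' @param max_coeff cap on each TI's multiplicity during the search (default 3)
#' @param budget node budget per realizability check (see [realize_parikh()])
#' @param combo_budget cap on combinations examined per seed TI; exhaustion is
#'   reported in `inconclusive`, never silent
#' @param verbose print one progress line per seed TI
#' @return list with `mis` (list of `manatee_invariant` objects) and
#'   `inconclusive` (combinations whose realizability check ran out of budget
#'   or seeds whose combination search was truncated, reported separately)
#' @export
manatee_invariants <- function(net, tis, max_coeff = 3, budget = 800,
                               combo_budget = 400, verbose = FALSE) {
  nti <- length(tis)
  if (nti == 0L) return(list(mis = list(), inconclusive = list()))
  tid <- net$transitions$id
  TIm <- do.call(rbind, lapply(tis, invariant_vector, ids = tid))

  # Which TIs truly produce tokens on a place (read arcs are not production).
  produces_place <- function(k, place) {
    sup <- tis[[k]]$support
    any(net$post_pure[place, sup] > 0)
  }

  realize_cache <- new.env(parent = emptyenv())
  check <- function(parikh) {
    key <- paste(parikh, collapse = ",")
    hit <- realize_cache[[key]]
    if (!is.null(hit)) return(hit)
    cnt <- parikh[parikh > 0]
    res <- realize_parikh(net, counts = cnt, budget = budget)
    realize_cache[[key]] <- res
    res
  }

  found <- list()          # key = parikh string -> mi record
  inconclusive <- list()

  for (seed in seq_len(nti)) {
    start <- integer(nti); start[seed] <- 1L
    frontier <- list(list(combo = start, pending = FALSE, parent_nfir = -1))
    seen <- new.env(parent = emptyenv())
    seen[[paste(start, collapse = ",")]] <- TRUE
    minimal_here <- list()  # realizable combos recorded for this seed
    examined <- 0L
    truncated <- FALSE

    while (length(frontier)) {
      nxt <- list()
      for (node in frontier) {
        combo <- node$combo
        if (examined >= combo_budget) { truncated <- TRUE; break }
        examined <- examined + 1L
        # skip if dominated by an already-recorded minimal combo of this seed
        dominated <- any(vapply(minimal_here,
                                function(mc) all(mc <= combo), logical(1)))
        if (dominated) next
        parikh <- as.vector(combo %*% TIm)
        names(parikh) <- tid
        res <- check(parikh)
        if (res$status == "realized") {
          minimal_here[[length(minimal_here) + 1L]] <- combo
          key <- paste(parikh, collapse = ",")
          if (is.null(found[[key]])) {
            found[[key]] <- list(ti_coefficients = stats::setNames(
                                   combo[combo > 0],
                                   as.character(which(combo > 0))),
                                 parikh = parikh[parikh > 0],
                                 witness = res$sequence)
          }
          next
        }
        # progress filter: an addition that enlarged the parent's firable set
        # is progress — typically a provider whose own syntheses fire. A
        # provider that still awaits another token (a mitochondrial cascade
        # without its initiator caspase) is granted one pending step; two
        # non-progress steps in a row end the branch.
        progressed <- res$n_firable > node$parent_nfir
        if (!progressed && node$pending) next
        if (res$status == "inconclusive") {
          # realizability undecided within the node budget: reported, and the
          # branch continues on the greedy stuck state so that supersets
          # (which often complete greedily) are still reached
          inconclusive[[length(inconclusive) + 1L]] <-
            list(ti_coefficients = stats::setNames(combo[combo > 0],
                                                   as.character(which(combo > 0))),
                 status = "inconclusive")
        }
        blocking <- res$blocking
        if (length(blocking) == 0L) {
          blocking <- .stuck_places(net, NULL, parikh[parikh > 0])
        }
        if (length(blocking) == 0L) next
        # branch on the blocking places whose trial-token injection unlocks
        # the largest part of the combination: the root requirement of a
        # deadlocked cycle unlocks the whole cycle, its downstream members
        # unlock nothing
        targets <- .pick_blocking_target(net, parikh, blocking)
        providers <- which(vapply(seq_len(nti), function(k)
          combo[k] < max_coeff &&
            any(vapply(targets, function(p) produces_place(k, p), logical(1))),
          logical(1)))
        for (k in providers) {
          child <- combo; child[k] <- child[k] + 1L
          ck <- paste(child, collapse = ",")
          if (!is.null(seen[[ck]])) next
          seen[[ck]] <- TRUE
          nxt[[length(nxt) + 1L]] <- list(combo = child,
                                          pending = !progressed,
                                          parent_nfir = res$n_firable)
        }
      }
      frontier <- nxt
      if (truncated) break
    }
    if (truncated) {
      inconclusive[[length(inconclusive) + 1L]] <-
        list(seed = seed, status = "search_truncated", examined = examined)
    }
    if (verbose) {
      message(sprintf("seed %d: %d minimal, %d combos examined%s", seed,
                      length(minimal_here), examined,
                      if (truncated) " (truncated)" else ""))
    }
  }

  mis <- unname(found)
  pi_places <- tryCatch(
    unique(unlist(lapply(place_invariants(net), `[[`, "support"))),
    error = function(e) character(0))
  mis <- lapply(mis, function(mi) {
    places <- induced_places(net, names(mi$parikh))
    mi$places <- places
    mi$is_pure <- length(intersect(places, pi_places)) == 0L
    structure(mi, class = "manatee_invariant")
  })
  # canonical order: number of TIs, then parikh support size, then support ids
  key <- vapply(mis, function(mi)
    sprintf("%04d|%06d|%s", length(mi$ti_coefficients), length(mi$parikh),
            paste(names(mi$parikh), collapse = ",")), character(1))
  mis <- mis[order(key, method = "radix")]
  for (i in seq_along(mis)) mis[[i]]$index <- i
  list(mis = mis, inconclusive = inconclusive)
}

.pick_blocking_target <- function(net, parikh, blocking) {
  if (length(blocking) == 1L) return(blocking)
  counts <- parikh[parikh > 0]
  gain <- vapply(blocking, function(p) {
    m <- net$marking
    m[p] <- m[p] + 1
    sum(.firable_set(net, m, counts))
  }, numeric(1))
  blocking[gain == max(gain)]
}

#' @export
print.manatee_invariant <- function(x, ...) {
  cat(sprintf("<MI%s> TIs {%s}, %d transitions%s\n",
              if (!is.null(x$index)) paste0("_", x$index) else "",
              paste(sprintf("%s x%g", names(x$ti_coefficients), x$ti_coefficients),
                    collapse = ", "),
              length(x$parikh),
              if (isTRUE(x$is_pure)) ", pure" else ""))
  invisible(x)
}

#' Classify a transition invariant as trivial, dissected, or complete
#'
#' A TI is *complete* when it is realizable on its own from the initial
#' marking, i.e. it appears as a singleton Manatee invariant. A complete TI is
#' *trivial* when it describes bare turnover: exactly one input and one output
#' transition with at most one place in between (e.g. synthesis and
#' degradation of a transcription factor). Everything else is a *dissected*
#' (incomplete) pathway that depends on tokens produced by other invariants.
#'
#' @param net a `petri_net`
#' @param ti one `transition_invariant`
#' @param mis list of MIs from [manatee_invariants()] (the `mis` component)
#' @return one of "trivial", "complete", "dissected"
#' @export
classify_ti <- function(net, ti, mis) {
  singleton <- vapply(mis, function(mi)
    length(mi$ti_coefficients) == 1L &&
      identical(names(mi$ti_coefficients), as.character(ti$index)) &&
      mi$ti_coefficients[[1]] == 1, logical(1))
  if (!any(singleton)) return("dissected")
  kinds <- net$transitions$kind[match(ti$support, net$transitions$id)]
  n_in <- sum(kinds == "input"); n_out <- sum(kinds == "output")
  n_places <- length(induced_places(net, ti$support))
  if (n_in == 1L && n_out == 1L && length(ti$support) == 2L && n_places <= 1L) {
    "trivial"
  } else "complete"
}

#' Classify all TIs of a net
#'
#' @inheritParams classify_ti
#' @param tis list of TIs
#' @return character vector of classifications, one per TI
#' @export
classify_tis <- function(net, tis, mis) {
  vapply(tis, classify_ti, character(1), net = net, mis = mis)
}

#' Export Manatee invariants to JSON
#'
#' @param mis list of MIs
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_manatee_json <- function(mis, path) {
  obj <- lapply(mis, function(mi)
    list(index = mi$index,
         ti_coefficients = as.list(mi$ti_coefficients),
         parikh = as.list(mi$parikh),
         witness = mi$witness,
         is_pure = mi$is_pure,
         outcome = mi$outcome %||% NULL))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
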