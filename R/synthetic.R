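#' Motif specification for synthetic Petri nets
#'
#' Each motif mirrors a structural pattern of open signal-transduction
#' models and has a closed-form expected invariant set (the "planted truth"):
#'
#' * `synthesis_degradation` — syn -> A -> deg; one TI \{syn, deg\}, no PI.
#' * `gene_expression_cycle` — a transcription factor binds a gene, releases
#'   it together with an mRNA, the mRNA is translated and the protein
#'   degraded; the gene is conserved: one PI of support 2 (gene, bound gene),
#'   carrying one token in the initial marking.
#' * `linear_cascade` — synthesis, `length` conversion steps, output; one TI
#'   with `length + 2` transitions.
#' * `complex_formation` — two synthesised monomers join and the complex is
#'   degraded; one TI over all four+ transitions.
#' * `feedback_loop` — a cascade step requires a catalyst place that its own
#'   downstream step regenerates; one PI over the catalyst pair, and the TI
#'   through the loop is dissected unless the catalyst holds a token.
#' * `provider_consumer` — a realizable provider flow feeds place X and a
#'   borrowing cycle on X; planted Manatee set: \{provider\} and
#'   \{provider + consumer\}, never \{consumer\} alone.
#'
#' @param kind motif kind (see above)
#' @param length cascade length (conversion steps) for `linear_cascade`
#' @param marked for `feedback_loop`: put a token on the catalyst, making the
#'   loop TI complete instead of dissected
#' @return a `motif_spec`
#' @export
motif_spec <- function(kind = c("synthesis_degradation", "gene_expression_cycle",
                                "linear_cascade", "complex_formation",
                                "feedback_loop", "provider_consumer"),
                       length = 3, marked = FALSE) {
  kind <- match.arg(kind)
  structure(list(kind = kind, length = length, marked = marked),
            class = "motif_spec")
}

#' Generate a Petri net from motif specifications
#'
#' Motifs are instantiated under namespaced ids (`m1_`, `m2_`, ...) and
#' composed disjointly, so the planted truth is the union of the per-motif
#' algebra. Deterministic: the seed only fixes the (currently
#' order-preserving) instantiation and is kept in the interface so wiring
#' variants stay reproducible.
#'
#' @param specs list of [motif_spec()] objects (a single spec is accepted)
#' @param seed integer seed
#' @return list with `net` (a `petri_net`) and `truth`: expected PI supports,
#'   TI supports, the subset of TI supports that are complete (realizable
#'   alone), expected MI count, and expected knockout-affected sets per
#'   synthesis transition
#' @export
generate_motif_net <- function(specs, seed = 1) {
  if (inherits(specs, "motif_spec")) specs <- list(specs)
  parts <- .with_seed(seed, lapply(seq_along(specs), function(i) {
    .build_motif(specs[[i]], prefix = sprintf("m%d_", i))
  }))
  places <- do.call(rbind, lapply(parts, `[[`, "places"))
  transitions <- do.call(rbind, lapply(parts, `[[`, "transitions"))
  arcs <- do.call(rbind, lapply(parts, `[[`, "arcs"))
  marking <- unlist(lapply(parts, `[[`, "marking"))
  net <- petri_net(places, transitions, arcs,
                   marking = marking[marking > 0])
  truth <- list(
    pi_supports = unlist(lapply(parts, function(p) p$truth$pi_supports),
                         recursive = FALSE),
    ti_supports = unlist(lapply(parts, function(p) p$truth$ti_supports),
                         recursive = FALSE),
    complete_ti_supports = unlist(lapply(parts, function(p) p$truth$complete),
                                  recursive = FALSE),
    n_mis = sum(vapply(parts, function(p) p$truth$n_mis, numeric(1))),
    knockout_affected = do.call(c, lapply(parts, function(p) p$truth$knockout))
  )
  truth$pi_supports <- lapply(truth$pi_supports, sort, method = "radix")
  truth$ti_supports <- lapply(truth$ti_supports, sort, method = "radix")
  truth$complete_ti_supports <- lapply(truth$complete_ti_supports, sort,
                                       method = "radix")
  list(net = net, truth = truth)
}

.build_motif <- function(spec, prefix) {
  p <- function(...) paste0(prefix, c(...))
  out <- list(marking = numeric(0))
  A <- function(source, target, weight = 1, read = FALSE)
    data.frame(source = source, target = target, weight = weight, read = read)
  switch(
    spec$kind,
    synthesis_degradation = {
      out$places <- data.frame(id = p("A"))
      out$transitions <- data.frame(id = p(c("syn", "deg")))
      out$arcs <- rbind(A(p("syn"), p("A")), A(p("A"), p("deg")))
      out$truth <- list(pi_supports = list(), ti_supports = list(p(c("syn", "deg"))),
                        complete = list(p(c("syn", "deg"))), n_mis = 1,
                        knockout = stats::setNames(list(p("A")), p("syn")))
    },
    gene_expression_cycle = {
      out$places <- data.frame(id = p(c("g", "TFg", "mRNA", "prot", "TF")))
      out$transitions <- data.frame(id = p(c("synTF", "bind", "release",
                                             "translate", "degTF", "degprot")))
      out$arcs <- rbind(
        A(p("synTF"), p("TF")),
        A(p("TF"), p("bind")), A(p("g"), p("bind")), A(p("bind"), p("TFg")),
        A(p("TFg"), p("release")), A(p("release"), p("g")),
        A(p("release"), p("TF")), A(p("release"), p("mRNA")),
        A(p("mRNA"), p("translate")), A(p("translate"), p("prot")),
        A(p("TF"), p("degTF")), A(p("prot"), p("degprot"))
      )
      out$marking <- stats::setNames(1, p("g"))
      # expression cycle borrows a TF token: dissected until combined with
      # the TF turnover TI, so the planted MI set is {turnover} and
      # {turnover + expression cycle}
      out$truth <- list(
        pi_supports = list(p(c("g", "TFg"))),
        ti_supports = list(p(c("synTF", "degTF")),
                           p(c("bind", "release", "translate", "degprot"))),
        complete = list(p(c("synTF", "degTF"))),
        n_mis = 2,
        knockout = stats::setNames(
          list(p(c("TF", "TFg", "g", "mRNA", "prot"))), p("synTF")))
    },
    linear_cascade = {
      k <- spec$length
      pl <- p(sprintf("A%d", seq_len(k + 1)))
      tr <- c(p("syn"), p(sprintf("t%d", seq_len(k))), p("out"))
      arcs <- A(p("syn"), pl[1])
      for (i in seq_len(k)) arcs <- rbind(arcs, A(pl[i], tr[i + 1]),
                                          A(tr[i + 1], pl[i + 1]))
      arcs <- rbind(arcs, A(pl[k + 1], p("out")))
      out$places <- data.frame(id = pl)
      out$transitions <- data.frame(id = tr)
      out$arcs <- arcs
      out$truth <- list(pi_supports = list(), ti_supports = list(sort(tr)),
                        complete = list(sort(tr)), n_mis = 1,
                        knockout = stats::setNames(list(sort(pl)), p("syn")))
    },
    complex_formation = {
      out$places <- data.frame(id = p(c("A", "B", "AB")))
      out$transitions <- data.frame(id = p(c("synA", "synB", "join", "degAB")))
      out$arcs <- rbind(
        A(p("synA"), p("A")), A(p("synB"), p("B")),
        A(p("A"), p("join")), A(p("B"), p("join")), A(p("join"), p("AB")),
        A(p("AB"), p("degAB"))
      )
      tiall <- p(c("synA", "synB", "join", "degAB"))
      out$truth <- list(pi_supports = list(), ti_supports = list(sort(tiall)),
                        complete = list(sort(tiall)), n_mis = 1,
                        knockout = stats::setNames(
                          list(p(c("A", "AB", "B")), p(c("A", "AB", "B"))),
                          p(c("synA", "synB"))))
    },
    feedback_loop = {
      # syn -> A; A + C -> t1 -> B; B -> t2 -> C + D; D -> deg
      out$places <- data.frame(id = p(c("A", "B", "C", "D")))
      out$transitions <- data.frame(id = p(c("syn", "t1", "t2", "deg")))
      out$arcs <- rbind(
        A(p("syn"), p("A")),
        A(p("A"), p("t1")), A(p("C"), p("t1")), A(p("t1"), p("B")),
        A(p("B"), p("t2")), A(p("t2"), p("C")), A(p("t2"), p("D")),
        A(p("D"), p("deg"))
      )
      if (spec$marked) out$marking <- stats::setNames(1, p("C"))
      ti <- sort(p(c("syn", "t1", "t2", "deg")))
      out$truth <- list(
        pi_supports = list(p(c("B", "C"))),
        ti_supports = list(ti),
        complete = if (spec$marked) list(ti) else list(),
        n_mis = if (spec$marked) 1 else 0,
        knockout = stats::setNames(
          list(if (spec$marked) p(c("A", "B", "C", "D")) else character(0)),
          p("syn")))
    },
    provider_consumer = {
      # provider: synP -> P -> tP -> X -> degX ; consumer cycle: X <-> Y
      out$places <- data.frame(id = p(c("P", "X", "Y")))
      out$transitions <- data.frame(id = p(c("synP", "tP", "degX", "tXY", "tYX")))
      out$arcs <- rbind(
        A(p("synP"), p("P")), A(p("P"), p("tP")), A(p("tP"), p("X")),
        A(p("X"), p("degX")),
        A(p("X"), p("tXY")), A(p("tXY"), p("Y")),
        A(p("Y"), p("tYX")), A(p("tYX"), p("X"))
      )
      prov <- sort(p(c("synP", "tP", "degX")))
      cons <- sort(p(c("tXY", "tYX")))
      out$truth <- list(
        pi_supports = list(),
        ti_supports = list(prov, cons),
        complete = list(prov),
        n_mis = 2,  # {provider} and {provider + consumer}
        knockout = stats::setNames(list(p(c("P", "X", "Y"))), p("synP")))
    },
    .stopf("unknown motif kind: %s", spec$kind)
  )
  out
}

#' Generate a seeded random Petri net
#'
#' Builds a connected bipartite net: a random spanning arrangement links all
#' places and transitions, then extra arcs are added until the requested
#' density is met. Weights are drawn from \{1, 2\}; optional read arcs are
#' added with probability `read_prob`. Identical seeds give identical nets.
#'
#' @param n_places,n_transitions vertex counts (>= 1)
#' @param arc_density fraction in (0, 1] of the |P| x |T| x 2 possible
#'   directed arcs to realise (spanning connectivity may exceed it)
#' @param seed integer seed
#' @param read_prob probability that an added arc becomes a read arc
#' @param marked_places number of places given one initial token
#' @return a `petri_net`
#' @export
generate_random_net <- function(n_places, n_transitions, arc_density = 0.3,
                                seed = 1, read_prob = 0, marked_places = 0) {
  stopifnot(n_places >= 1, n_transitions >= 1,
            arc_density > 0, arc_density <= 1)
  .with_seed(seed, {
    pids <- sprintf("p%02d", seq_len(n_places))
    tids <- sprintf("t%02d", seq_len(n_transitions))
    arcs <- list()
    key_seen <- new.env(parent = emptyenv())
    add <- function(s, t, w, read = FALSE) {
      k <- paste(s, t)
      if (!is.null(key_seen[[k]])) return(FALSE)
      key_seen[[k]] <- TRUE
      arcs[[length(arcs) + 1L]] <<- data.frame(source = s, target = t,
                                               weight = w, read = read)
      TRUE
    }
    # connect every vertex: walk alternating place/transition
    verts <- c(pids, tids)
    is_place <- c(rep(TRUE, n_places), rep(FALSE, n_transitions))
    ordv <- sample(length(verts))
    connected <- ordv[1]
    for (v in ordv[-1]) {
      partner_pool <- connected[is_place[connected] != is_place[v]]
      if (length(partner_pool) == 0L) {
        # bridge via a random vertex of the other type (may be unconnected yet)
        partner_pool <- which(is_place != is_place[v])
      }
      u <- partner_pool[sample.int(length(partner_pool), 1)]
      a <- verts[v]; b <- verts[u]
      if (stats::runif(1) < 0.5) add(a, b, sample(1:2, 1)) else add(b, a, sample(1:2, 1))
      connected <- c(connected, v)
    }
    target_arcs <- max(length(arcs), ceiling(arc_density * n_places * n_transitions * 2))
    guard <- 0L
    while (length(arcs) < target_arcs && guard < 50L * target_arcs) {
      guard <- guard + 1L
      pp <- pids[sample.int(n_places, 1)]
      tt <- tids[sample.int(n_transitions, 1)]
      w <- sample(1:2, 1)
      if (stats::runif(1) < read_prob) {
        if (is.null(key_seen[[paste(pp, tt)]]) &&
            is.null(key_seen[[paste(tt, pp)]])) {
          add(pp, tt, w, read = TRUE)
          add(tt, pp, w, read = TRUE)
        }
      } else if (stats::runif(1) < 0.5) add(pp, tt, w) else add(tt, pp, w)
    }
    marking <- NULL
    if (marked_places > 0) {
      mp <- sample(pids, min(marked_places, n_places))
      marking <- stats::setNames(rep(1, length(mp)), mp)
    }
    petri_net(pids, tids, do.call(rbind, arcs), marking = marking)
  })
}
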