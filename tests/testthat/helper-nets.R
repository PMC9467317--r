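# Shared fixture nets and independent oracles, all built in code.

# Five-place example: weighted arc (2), a read arc, two transitions.
example_net <- function() {
  petri_net(
    places = c("p1", "p2", "p3", "p4", "p5"),
    transitions = c("t1", "t2"),
    arcs = data.frame(
      source = c("p1", "p2", "t1", "p3", "p4", "t2"),
      target = c("t1", "t1", "p3", "t2", "t2", "p5"),
      weight = c(2, 1, 1, 1, 1, 1),
      read = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
    ),
    marking = c(p1 = 2, p2 = 1, p4 = 1)
  )
}

chain_net <- function() {
  petri_net("A", c("syn", "deg"),
            data.frame(source = c("syn", "A"), target = c("A", "deg")))
}

# Independent incidence oracle: naive accumulation over the arc list.
incidence_oracle <- function(net) {
  C <- matrix(0, nrow(net$places), nrow(net$transitions),
              dimnames = list(net$places$id, net$transitions$id))
  a <- net$arcs[!net$arcs$read, , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    if (a$source[i] %in% net$places$id) {
      C[a$source[i], a$target[i]] <- C[a$source[i], a$target[i]] - a$weight[i]
    } else {
      C[a$target[i], a$source[i]] <- C[a$target[i], a$source[i]] + a$weight[i]
    }
  }
  C
}

# Bounded exhaustive invariant oracle: all x with entries in 0..max_coef and
# M x = 0 (M = C for PIs over rows? No: pass the matrix whose rows are the
# constraints and whose columns are the variables), reduced to gcd-1 vectors
# with minimal support.
brute_invariants <- function(M, max_coef = 4) {
  n <- ncol(M)
  grid <- as.matrix(expand.grid(rep(list(0:max_coef), n)))
  keep <- rowSums(abs(grid %*% t(M))) == 0 & rowSums(grid) > 0
  X <- grid[keep, , drop = FALSE]
  if (nrow(X) == 0L) return(list())
  gcdv <- function(v) Reduce(function(a, b) { while (b) { r <- a %% b; a <- b; b <- r }; a },
                             abs(v[v != 0]))
  X <- t(apply(X, 1, function(r) r / gcdv(r)))
  X <- X[!duplicated(X), , drop = FALSE]
  S <- X != 0
  sz <- rowSums(S)
  drop <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(X))) {
      if (i != j && !drop[j] && sz[i] < sz[j] && all(S[j, ][S[i, ]])) drop[j] <- TRUE
    }
  }
  X <- X[!drop, , drop = FALSE]
  colnames(X) <- colnames(M)
  lapply(seq_len(nrow(X)), function(i) X[i, ])
}

# Canonical form of an invariant list for set comparison.
inv_canon <- function(invs, ids) {
  out <- lapply(invs, function(v) {
    if (is.list(v)) x <- invariant_vector(v, ids) else {
      x <- stats::setNames(numeric(length(ids)), ids); x[names(v)[v > 0]] <- v[v > 0]
    }
    paste(x, collapse = ",")
  })
  sort(unlist(out))
}

# Naive O(n^3) UPGMA reference: size-weighted average linkage, d/2 heights,
# lexicographically smallest label pair on ties. Returns the cophenetic
# distance matrix (on the height scale).
upgma_oracle_cophenetic <- function(D) {
  labs <- rownames(D)
  n <- length(labs)
  clusters <- lapply(seq_len(n), function(i) labs[i])
  sizes <- rep(1, n)
  d <- D
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d[i, j] < best$d - 1e-12 ||
            (abs(d[i, j] - best$d) <= 1e-12 &&
             paste(key, collapse = "|") < paste(best$key, collapse = "|"))) {
          best <- list(i = i, j = j, d = d[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    merged <- c(clusters[[i]], clusters[[j]])
    newd <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_along(clusters), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    clusters <- c(clusters[keep], list(merged))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    d <- d2
  }
  coph
}

# Lazily computed full analysis of the bundled model, shared across test
# files (invariants in seconds, Manatee construction dominates).
tnfr1_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      loaded <- load_tnfr1()
      net <- loaded$net
      tis <- transition_invariants(net)
      pis <- place_invariants(net)
      mi <- manatee_invariants(net, tis)
      cache <<- list(net = net, manifest = loaded$manifest, tis = tis,
                     pis = pis, mis = mi$mis, inconclusive = mi$inconclusive)
    }
    cache
  }
})
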