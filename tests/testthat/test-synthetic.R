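test_that("generators are deterministic given a seed", {
  a <- generate_random_net(5, 5, 0.3, seed = 1)
  b <- generate_random_net(5, 5, 0.3, seed = 1)
  expect_identical(a$arcs, b$arcs)
  expect_identical(a$marking, b$marking)
  c <- generate_random_net(5, 5, 0.3, seed = 2)
  expect_false(identical(a$arcs, c$arcs))

  m1 <- generate_motif_net(list(motif_spec("linear_cascade", length = 3),
                                motif_spec("feedback_loop", marked = TRUE)),
                           seed = 9)
  m2 <- generate_motif_net(list(motif_spec("linear_cascade", length = 3),
                                motif_spec("feedback_loop", marked = TRUE)),
                           seed = 9)
  expect_identical(m1$net$arcs, m2$net$arcs)
  expect_identical(m1$truth, m2$truth)
})

test_that("random nets are bipartite and connected with positive small weights", {
  for (seed in 1:8) {
    net <- generate_random_net(6, 7, 0.3, seed = seed, read_prob = 0.2)
    a <- net$arcs
    src_p <- a$source %in% net$places$id
    tgt_p <- a$target %in% net$places$id
    expect_true(all(xor(src_p, tgt_p)))
    expect_true(all(a$weight %in% c(1, 2)))
    # connectivity: undirected reachability covers every vertex
    verts <- c(net$places$id, net$transitions$id)
    adj <- unique(rbind(a[, c("source", "target")],
                        stats::setNames(a[, c("target", "source")],
                                        c("source", "target"))))
    reach <- verts[1]
    repeat {
      nxt <- unique(adj$target[adj$source %in% reach])
      if (all(nxt %in% reach)) break
      reach <- union(reach, nxt)
    }
    expect_setequal(reach, verts)
  }
})

test_that("planted invariants are recovered exactly across motif nets and seeds", {
  specs <- list(
    list(motif_spec("synthesis_degradation")),
    list(motif_spec("gene_expression_cycle")),
    list(motif_spec("linear_cascade", length = 4)),
    list(motif_spec("complex_formation")),
    list(motif_spec("feedback_loop")),
    list(motif_spec("feedback_loop", marked = TRUE)),
    list(motif_spec("provider_consumer")),
    list(motif_spec("gene_expression_cycle"), motif_spec("linear_cascade", length = 2)),
    list(motif_spec("synthesis_degradation"), motif_spec("provider_consumer"),
         motif_spec("complex_formation"))
  )
  n_checked <- 0
  for (sp in specs) {
    for (seed in 1:12) {
      g <- generate_motif_net(sp, seed = seed)
      tis <- transition_invariants(g$net)
      pis <- place_invariants(g$net)
      expect_identical(lapply(tis, `[[`, "support"),
                       g$truth$ti_supports[order(vapply(g$truth$ti_supports,
                         function(s) sprintf("%06d|%s", length(s),
                                             paste(s, collapse = ",")),
                         character(1)), method = "radix")])
      expect_identical(lapply(pis, `[[`, "support"),
                       g$truth$pi_supports[order(vapply(g$truth$pi_supports,
                         function(s) sprintf("%06d|%s", length(s),
                                             paste(s, collapse = ",")),
                         character(1)), method = "radix")])
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("planted MI counts and complete subsets are recovered", {
  for (kind in c("synthesis_degradation", "gene_expression_cycle",
                 "provider_consumer", "complex_formation")) {
    g <- generate_motif_net(motif_spec(kind))
    tis <- transition_invariants(g$net)
    res <- manatee_invariants(g$net, tis)
    expect_identical(length(res$mis), as.integer(g$truth$n_mis), info = kind)
    singles <- lapply(Filter(function(m) length(m$ti_coefficients) == 1L &&
                               m$ti_coefficients[[1]] == 1, res$mis),
                      function(m) sort(names(m$parikh)))
    expect_setequal(singles, g$truth$complete_ti_supports)
  }
  # the unmarked feedback loop is dissected and yields no MI at all
  g <- generate_motif_net(motif_spec("feedback_loop"))
  expect_length(manatee_invariants(g$net, transition_invariants(g$net))$mis, 0L)
})

test_that("planted knockout-affected sets match computed ones", {
  for (kind in c("synthesis_degradation", "gene_expression_cycle",
                 "complex_formation", "provider_consumer")) {
    g <- generate_motif_net(motif_spec(kind))
    mis <- manatee_invariants(g$net, transition_invariants(g$net))$mis
    for (syn in names(g$truth$knockout_affected)) {
      got <- knockout_affected(g$net, mis, syn)
      expect_setequal(got, g$truth$knockout_affected[[syn]])
    }
  }
})
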