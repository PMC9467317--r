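# Small three-branch fixture: one synthesis feeds two branches, a second
# synthesis feeds a third; gives five easily hand-countable MIs.
branch_net <- function() {
  petri_net(
    places = c("A", "B1", "B2", "C"),
    transitions = c("synA", "tA1", "tA2", "d1", "d2", "synC", "dC"),
    arcs = data.frame(
      source = c("synA", "A", "tA1", "A", "tA2", "B1", "B2", "synC", "C"),
      target = c("A", "tA1", "B1", "tA2", "B2", "d1", "d2", "C", "dC")
    )
  )
}

branch_analysis <- function() {
  net <- branch_net()
  tis <- transition_invariants(net)
  list(net = net, tis = tis, mis = manatee_invariants(net, tis)$mis)
}

test_that("knockout affected sets match delete-and-recompute on synthetic nets", {
  an <- branch_analysis()
  for (knock in c("synA", "synC")) {
    got <- knockout_affected(an$net, an$mis, knock)
    # structural oracle: physically delete the transition, recompute MIs
    keep <- an$net$transitions$id != knock
    del <- petri_net(an$net$places, an$net$transitions[keep, c("id", "name")],
                     an$net$arcs[an$net$arcs$source != knock &
                                   an$net$arcs$target != knock, ],
                     marking = an$net$marking[an$net$marking > 0])
    del_tis <- transition_invariants(del)
    del_mis <- manatee_invariants(del, del_tis)$mis
    covered <- sort(unique(unlist(lapply(an$mis, `[[`, "places"))))
    alive <- sort(unique(unlist(lapply(del_mis, `[[`, "places"))))
    expect_identical(got, setdiff(covered, alive))
  }

  for (seed in 1:4) {
    g <- generate_motif_net(list(motif_spec("linear_cascade", length = 2),
                                 motif_spec("complex_formation")), seed = seed)
    tis <- transition_invariants(g$net)
    mis <- manatee_invariants(g$net, tis)$mis
    syn <- g$net$transitions$id[g$net$transitions$kind == "input"][1]
    got <- knockout_affected(g$net, mis, syn)
    keep <- g$net$transitions$id != syn
    del <- petri_net(g$net$places, g$net$transitions[keep, c("id", "name")],
                     g$net$arcs[g$net$arcs$source != syn & g$net$arcs$target != syn, ],
                     marking = g$net$marking[g$net$marking > 0])
    del_mis <- manatee_invariants(del, transition_invariants(del))$mis
    covered <- sort(unique(unlist(lapply(mis, `[[`, "places"))))
    alive <- sort(unique(unlist(lapply(del_mis, `[[`, "places"))))
    expect_identical(got, setdiff(covered, alive))
  }
})

test_that("knocking a transition in no MI affects nothing", {
  an <- branch_analysis()
  # add an isolated dead-end transition: consumes nothing produced
  net2 <- petri_net(c(an$net$places$id, "Z"),
                    c(an$net$transitions$id, "tz"),
                    rbind(an$net$arcs, data.frame(source = "Z", target = "tz",
                                                  weight = 1, read = FALSE)))
  expect_identical(knockout_affected(net2, an$mis, "tz"), character(0))
})

test_that("knockout monotonicity: union experiments affect at least the union", {
  an <- tnfr1_analysis()
  pairs <- list(c("syn_TNF", "syn_MLKL"), c("syn_RIP3", "trans_XIAP"),
                c("syn_FADD", "syn_BAX"), c("syn_CYLD", "trans_A20"))
  for (p in pairs) {
    a <- knockout_affected(an$net, an$mis, p[1])
    b <- knockout_affected(an$net, an$mis, p[2])
    ab <- knockout_affected(an$net, an$mis,
                            knockout_experiment(an$net, p, allow_any = TRUE))
    expect_true(all(union(a, b) %in% ab))
  }
})

test_that("a knocked synthesis always affects its direct product place", {
  an <- tnfr1_analysis()
  exps <- tnfr1_experiments(an$net, an$manifest)
  columns <- colnames(knockout_matrix(an$net, an$mis, exps)$affected)
  for (e in exps) {
    prod <- rownames(an$net$post)[an$net$post[, e$knocked] > 0]
    aff <- knockout_affected(an$net, an$mis, e)
    covered <- unique(unlist(lapply(an$mis, `[[`, "places")))
    expect_true(all(intersect(prod, covered) %in% aff),
                info = e$name)
  }
})

test_that("knockout matrix defaults exclude PI places and validate inputs", {
  an <- branch_analysis()
  km <- knockout_matrix(an$net, an$mis)
  expect_identical(rownames(km$affected), c("synA", "synC"))
  expect_identical(colnames(km$affected), c("A", "B1", "B2", "C"))
  expect_identical(unname(km$affected["synA", ]), c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(unname(km$affected["synC", ]), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(knockout_matrix(an$net, an$mis, experiments = list()),
               "empty experiment")
  expect_error(knockout_experiment(an$net, "tA1"), "input")
})

test_that("the downstream-only filter keeps reachable places only", {
  an <- branch_analysis()
  # synA reaches A, B1, B2 but not C; global and downstream semantics agree
  # here because the affected set is already downstream
  glob <- knockout_affected(an$net, an$mis, "synA")
  down <- knockout_affected(an$net, an$mis, "synA", downstream_only = TRUE)
  expect_identical(down, glob)
  expect_false("C" %in% down)
  # a knockout whose global effect includes an upstream provider place is
  # trimmed: knock the consumer cycle of a provider/consumer motif
  g <- generate_motif_net(motif_spec("provider_consumer"))
  mis <- manatee_invariants(g$net, transition_invariants(g$net))$mis
  glob2 <- knockout_affected(g$net, mis, "m1_tXY")
  down2 <- knockout_affected(g$net, mis, "m1_tXY", downstream_only = TRUE)
  expect_true(all(down2 %in% glob2))
  expect_false("m1_P" %in% down2)  # upstream of the knocked transition
})

test_that("presets expand to the documented multi-knockouts", {
  an <- tnfr1_analysis()
  sm <- multiple_knockout_preset(an$net, "smac_mimetic")
  expect_setequal(sm$knocked, c("trans_XIAP", "syn_cIAP"))
  chx <- multiple_knockout_preset(an$net, "cycloheximide")
  expect_setequal(chx$knocked, c("trans_IkB", "trans_A20", "trans_XIAP",
                                 "trans_cFLIPL", "trans_BCL2"))
  expect_error(multiple_knockout_preset(an$net, "nope"), "unknown preset")
  # a singleton preset equals the corresponding single knockout
  single <- knockout_affected(an$net, an$mis, "trans_XIAP")
  viaexp <- knockout_affected(an$net, an$mis,
                              knockout_experiment(an$net, "trans_XIAP",
                                                  allow_any = TRUE))
  expect_identical(single, viaexp)
})

test_that("protein ranking fractions equal manual counts on the fixture", {
  an <- branch_analysis()
  km <- knockout_matrix(an$net, an$mis)
  rk <- rank_proteins(km)
  # MIs: {synA,tA1,d1}, {synA,tA2,d2}, {synC,dC}: synA kills 2 of 3
  expect_equal(rk$mi_fraction[rk$experiment == "synA"], 2 / 3)
  expect_equal(rk$mi_fraction[rk$experiment == "synC"], 1 / 3)
  expect_equal(rk$place_fraction[rk$experiment == "synA"], 3 / 4)
  expect_identical(rk$experiment[1], "synA")
  # a protein in no MI ranks last at zero
  rk2 <- rank_proteins(km, by = "place_fraction")
  expect_identical(rk2$experiment[1], "synA")
})

test_that("knockout matrix exports round-trip through CSV and long TSV", {
  an <- branch_analysis()
  km <- knockout_matrix(an$net, an$mis)
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_knockout_matrix(km, wide)
  write_knockout_matrix(km, long, "long")
  w <- utils::read.csv(wide, check.names = FALSE)
  expect_identical(w$experiment, rownames(km$affected))
  expect_identical(unname(as.matrix(w[, -1]) == 1), unname(km$affected))
  l <- utils::read.delim(long)
  expect_identical(nrow(l), length(km$affected))
})
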