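test_that("incidence matrix matches hand-computed and oracle values", {
  net <- example_net()
  C <- incidence_matrix(net)
  expect_identical(unname(C[, "t1"]), c(-2, -1, 1, 0, 0))
  expect_identical(unname(C[, "t2"]), c(0, 0, 0, -1, 1))
  expect_identical(C["p3", "t2"], 0)  # read-arc pair contributes nothing

  empty <- petri_net(c("a", "b"), c("t"), arcs = NULL)
  expect_true(all(incidence_matrix(empty) == 0))

  for (seed in 1:5) {
    rnd <- generate_random_net(5, 5, 0.3, seed = seed, read_prob = 0.1)
    expect_identical(incidence_matrix(rnd), incidence_oracle(rnd))
  }
})

test_that("net construction validates bipartiteness, ids, and weights", {
  expect_error(petri_net(c("a", "a"), "t"), "duplicate")
  expect_error(petri_net("a", "a"), "shared")
  expect_error(petri_net(c("a", "b"), "t",
                         data.frame(source = "a", target = "b")), "bipartite")
  expect_error(petri_net("a", "t",
                         data.frame(source = "a", target = "t", weight = 0)),
               "positive")
  expect_error(petri_net("a", "t", data.frame(source = "a", target = "t"),
                         marking = c(zz = 1)), "unknown")
})

test_that("enabling follows the token threshold rule, read arcs included", {
  net <- example_net()
  expect_true(is_enabled(net, t = "t1"))
  expect_false(is_enabled(net, t = "t2"))  # p3 empty despite p4 marked
  expect_error(is_enabled(net, t = "nope"), "unknown transition")

  # input transition is enabled at any marking, including all-zero
  syn <- petri_net("A", "syn", data.frame(source = "syn", target = "A"))
  expect_true(is_enabled(syn, c(A = 0), "syn"))
})

test_that("firing consumes and produces simultaneously; read arcs are neutral", {
  net <- example_net()
  m1 <- fire(net, t = "t1")
  expect_identical(unname(m1), c(0, 0, 1, 1, 0))
  m2 <- fire(net, m1, "t2")
  expect_identical(unname(m2), c(0, 0, 1, 0, 1))
  expect_identical(m2[["p3"]], 1)  # tested place retained
  expect_error(fire(net, t = "t2"), "not enabled")

  syn <- petri_net("A", "syn", data.frame(source = "syn", target = "A"))
  expect_identical(fire(syn, c(A = 0), "syn")[["A"]], 1)
})

test_that("token conservation: reverse-applying the incidence column restores m", {
  for (seed in 1:5) {
    net <- generate_random_net(6, 6, 0.3, seed = seed, read_prob = 0.15,
                               marked_places = 3)
    C <- incidence_matrix(net)
    m <- net$marking
    for (t in enabled_transitions(net, m)) {
      m2 <- fire(net, m, t)
      expect_identical(unname(m2 - C[, t]), unname(m))
    }
  }
})

test_that("markings never go negative on random firing walks", {
  for (seed in 1:10) {
    net <- generate_random_net(5, 6, 0.35, seed = seed, marked_places = 3)
    walk <- withr::with_seed(seed, random_walk(net, steps = 60))
    expect_true(all(walk$markings >= 0))
  }
})

test_that("induced subnetwork equals a brute-force adjacency scan", {
  m <- load_tnfr1()
  sub <- induced_subnetwork(m$net, c("t_ciib", "t_casp8_b", "t_ciib_act"))
  expect_setequal(sub$transitions$id, c("t_ciib", "t_casp8_b", "t_ciib_act"))
  expect_true(all(c("CIIb", "CASP8", "TRADD.RIP1", "FADD.ProC8") %in% sub$places$id))

  empty <- induced_subnetwork(m$net, character(0))
  expect_identical(nrow(empty$places), 0L)

  for (seed in 1:5) {
    net <- generate_random_net(6, 6, 0.3, seed = seed)
    sup <- withr::with_seed(seed, sample(net$transitions$id, 3))
    got <- induced_places(net, sup)
    want <- sort(unique(c(
      net$arcs$source[net$arcs$target %in% sup & net$arcs$source %in% net$places$id],
      net$arcs$target[net$arcs$source %in% sup & net$arcs$target %in% net$places$id])))
    expect_identical(got, want)
  }
})

test_that("logical place copies merge to one vertex", {
  net <- petri_net(
    places = data.frame(id = c("A1", "A2", "B"), name = c("A", "A", "B"),
                        logical_copy = c(FALSE, TRUE, FALSE)),
    transitions = c("t1", "t2"),
    arcs = data.frame(source = c("t1", "A2"), target = c("A1", "t2")),
    marking = c(A1 = 1)
  )
  merged <- merge_logical_places(net)
  expect_identical(nrow(merged$places), 2L)
  expect_true(is_enabled(merged, t = "t2"))
})
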