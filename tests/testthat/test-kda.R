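make_profile <- function(values) {
  structure(list(h = 1L, values = values, mu_bar = mean(values),
                 sigma_mu = pop_sd(values)),
            class = "hln_profile")
}

test_that("candidate selection applies the strict mean + SD rule", {
  # values {5,1,1,1}: mean 2, population SD sqrt(3), cutoff ~3.732 -> only a
  prof <- make_profile(c(a = 5L, b = 1L, c = 1L, d = 1L))
  expect_equal(select_candidate_drivers(prof), "a")

  # all equal: SD 0, strict > fails
  expect_equal(select_candidate_drivers(make_profile(c(a = 3L, b = 3L, c = 3L))),
               character())

  # two-node chain at h=1: values {1,0}, cutoff exactly 1.0, tie excluded
  chain <- gene_network("a", "b")
  expect_equal(select_candidate_drivers(h_layer_neighborhood(chain, 1)),
               character())
})

test_that("candidate and degree cutoffs are exactly recomputable on random profiles", {
  for (seed in 1:30) {
    set.seed(seed)
    net <- random_digraph(sample(10:40, 1), 0.1, seed = seed + 100)
    prof <- h_layer_neighborhood(net, 2)
    cand <- select_candidate_drivers(prof)
    cutoff <- mean(prof$values) + pop_sd(prof$values)
    expect_equal(prof$mu_bar + prof$sigma_mu, cutoff, tolerance = 1e-12)
    expect_setequal(cand, names(prof$values)[prof$values > cutoff])

    od <- out_degrees(net)
    deg_cut <- mean(od$values) + 2 * pop_sd(od$values)
    expect_setequal(global_by_out_degree(net),
                    names(od$values)[od$values > deg_cut])
  }
})

test_that("root-node classification partitions candidates by h-hop reachability", {
  chain3 <- gene_network(c("a", "b"), c("b", "c"))
  cls <- classify_drivers(chain3, c("a", "c"), h = 2)
  expect_equal(cls$global, "a")
  expect_equal(cls$local, "c")
  # at h=1 a no longer reaches c
  cls1 <- classify_drivers(chain3, c("a", "c"), h = 1)
  expect_setequal(cls1$global, c("a", "c"))

  expect_equal(classify_drivers(chain3, "b", h = 2)$global, "b")

  two_comp <- gene_network(c("a", "x"), c("b", "y"))
  cls2 <- classify_drivers(two_comp, c("a", "x"), h = 3)
  expect_setequal(cls2$global, c("a", "x"))
  expect_equal(cls2$local, character())

  expect_error(classify_drivers(chain3, "nope", h = 2), "nope")

  # partition invariant on random graphs
  for (seed in 1:10) {
    net <- random_digraph(20, 0.15, seed = seed)
    prof <- h_layer_neighborhood(net, 2)
    cand <- select_candidate_drivers(prof)
    cls <- classify_drivers(net, cand, h = 2)
    expect_setequal(c(cls$global, cls$local), cand)
    expect_length(intersect(cls$global, cls$local), 0)
  }
})

test_that("indegree0 root mode calls sources global", {
  chain3 <- gene_network(c("a", "b"), c("b", "c"))
  cls <- classify_drivers(chain3, c("a", "c"), h = 1, root_mode = "indegree0")
  expect_equal(cls$global, "a")  # c has an incoming edge
  expect_equal(cls$local, "c")
})

test_that("out-degree rule: star by hand, regular digraph empty", {
  star <- gene_network(rep("hub", 9), paste0("leaf", 1:9))
  # degrees {9, 0 x 9}: mean 0.9, population SD 2.7, cutoff 6.3
  expect_equal(global_by_out_degree(star), "hub")

  ring <- gene_network(letters[1:5], letters[c(2:5, 1)])  # 1-regular
  expect_equal(global_by_out_degree(ring), character())
})

test_that("run_kda is a pure function of (net, seeds, h) with consistent thresholds", {
  net <- random_digraph(40, 0.08, seed = 3)
  seeds <- net$nodes[1:10]
  r1 <- run_kda(net, seeds, h = 2)
  # permuting the edge rows leaves the result identical
  set.seed(1)
  perm <- sample(nrow(net$edges))
  net_perm <- gene_network(net$edges$from[perm], net$edges$to[perm],
                           nodes = sample(net$nodes))
  r2 <- run_kda(net_perm, rev(seeds), h = 2)
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$global_drivers, r2$global_drivers)
  expect_identical(r1$outdegree_globals, r2$outdegree_globals)
  expect_identical(r1$thresholds, r2$thresholds)

  # stored thresholds recompute from the stored vectors to 1e-12
  expect_equal(r1$thresholds$hln_cutoff,
               mean(r1$profile$values) + pop_sd(r1$profile$values),
               tolerance = 1e-12)
  expect_equal(r1$thresholds$degree_cutoff,
               mean(r1$out_degree) + 2 * pop_sd(r1$out_degree),
               tolerance = 1e-12)
  # every candidate is strictly above the cutoff
  expect_true(all(r1$profile$values[r1$candidates] > r1$thresholds$hln_cutoff))
  # global/local partition candidates
  expect_setequal(c(r1$global_drivers, r1$local_drivers), r1$candidates)
})

test_that("run_kda handles edgeless networks and absent seeds", {
  iso <- gene_network(nodes = letters[1:6])
  res <- run_kda(iso, c("a", "b"), h = 2)
  expect_equal(res$candidates, character())
  expect_equal(res$global_drivers, character())
  expect_equal(res$outdegree_globals, character())

  net <- gene_network("a", "b")
  expect_warning(res2 <- run_kda(net, c("a", "zz"), h = 1), "dropped")
  expect_equal(res2$seed_genes, "a")
  expect_error(suppressWarnings(run_kda(net, "zz", h = 1)), "no seed genes")
})

test_that("a planted hub regulating most seed genes is recovered as a driver", {
  sim <- generate_planted_network(n_nodes = 540, n_drivers = 1, fanout = 30,
                                  background_edge_prob = 0.002, seed = 1)
  hub <- sim$truth$planted_drivers
  seeds <- c(sim$truth$driver_targets,
             setdiff(sim$network$nodes, c(hub, sim$truth$driver_targets))[1:10])
  res <- suppressWarnings(run_kda(sim$network, seeds, h = 2))
  expect_true(hub %in% res$candidates)
  expect_true(hub %in% res$global_drivers)
  expect_true(hub %in% res$outdegree_globals)
})

test_that("enlarging h never shrinks any node's subnetwork HLN", {
  net <- random_digraph(35, 0.08, seed = 9)
  seeds <- net$nodes[1:8]
  r2 <- run_kda(net, seeds, h = 2)
  r3 <- run_kda(net, seeds, h = 3)
  common <- intersect(names(r2$profile$values), names(r3$profile$values))
  expect_true(all(r3$profile$values[common] >= r2$profile$values[common]))
})

test_that("the per-gene result table is coherent", {
  net <- random_digraph(30, 0.1, seed = 13)
  res <- run_kda(net, net$nodes[1:6], h = 2)
  df <- as.data.frame(res)
  expect_setequal(df$gene[df$is_candidate], res$candidates)
  expect_setequal(df$gene[df$driver_class == "global"], res$global_drivers)
  expect_setequal(df$gene[df$passes_outdegree_rule], res$outdegree_globals)
  expect_true(all(df$driver_class[!df$is_candidate] == "none"))
})
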