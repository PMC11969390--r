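test_that("toolkit entropy matches closed forms and the brute-force oracle", {
  expect_equal(toolkit_entropy(c("A_1.1", "A_1.2", "A_1.3")), 0)
  expect_equal(toolkit_entropy(initial_toolkit()), log(4))
  # equal per-lineage fitness mass (2.05 each): weighted also log 4
  expect_equal(toolkit_entropy(initial_toolkit(), weighted = TRUE), log(4))
  # counts (4, 4, 0, 0) -> log 2
  kit44 <- c("A_1.1", "A_1.2", "A_1.3", "A_2.2",
             "B_1.1", "B_1.2", "B_1.3", "B_2.2")
  expect_equal(toolkit_entropy(kit44), log(2))
  expect_error(toolkit_entropy(character(0)), "non-empty")

  set.seed(19)
  for (k in 1:300) {
    kit <- random_toolkit(sample(1:14, 1))
    u <- toolkit_entropy(kit)
    w <- toolkit_entropy(kit, weighted = TRUE)
    expect_equal(u, oracle_entropy(kit))
    expect_equal(w, oracle_entropy(kit, weighted = TRUE))
    expect_gte(u, 0); expect_lte(u, log(4) + 1e-12)
    expect_gte(w, 0); expect_lte(w, log(4) + 1e-12)
    # zero iff single lineage, in both weightings
    single <- length(unique(parse_tools(kit)$lineage)) == 1L
    expect_identical(u < 1e-12, single)
    expect_identical(w < 1e-12, single)
  }
})

test_that("group entropy is the mean of member entropies", {
  kits <- list(c("A_1.1", "A_1.2"), initial_toolkit())
  expect_equal(group_entropy(kits), log(4) / 2)
  expect_equal(group_entropy(rep(list(initial_toolkit()), 5)), log(4))
  expect_equal(group_entropy(list(c("B_1.1"), c("C_1.2", "C_1.1"))), 0)
})

test_that("pairwise differentiation agrees with brute force", {
  same <- rep(list(initial_toolkit()), 4)
  out <- pairwise_differentiation(same)
  expect_equal(out$distances, rep(0, 6))
  expect_equal(out$mean, 0)

  kits <- list(c("A_1.1", "A_1.2", "B_1.1"),
               c("A_1.2", "B_1.1", "B_1.2"),
               c("C_1.1", "C_1.2", "D_1.1"))
  out <- pairwise_differentiation(kits)
  expect_equal(out$distances, c(0.5, 1, 1))
  expect_equal(out$mean, mean(c(0.5, 1, 1)))
  expect_equal(out$se, sd(c(0.5, 1, 1)) / sqrt(3))

  set.seed(23)
  kits <- replicate(12, random_toolkit(sample(2:9, 1)), simplify = FALSE)
  out <- pairwise_differentiation(kits)
  brute <- unlist(lapply(seq_len(11), function(i)
    vapply((i + 1):12, function(j) oracle_jaccard(kits[[i]], kits[[j]]),
           numeric(1))))
  expect_equal(sort(out$distances), sort(brute))

  # groups with identical union toolkits are indistinguishable regardless of
  # internal diversity
  g1 <- list(c("A_1.1", "B_1.1"), c("C_1.1", "D_1.1"))
  g2 <- list(c("A_1.1", "B_1.1", "C_1.1", "D_1.1"))
  u1 <- unique(unlist(g1)); u2 <- unique(unlist(g2))
  expect_equal(jaccard(u1, u2), 0)
})

test_that("network metrics match graph enumeration", {
  # initial default network: 15 disconnected complete graphs of 20
  pop <- build_population(scenario_config("i"))
  nm <- network_metrics(pop$network)
  expect_equal(nm$between_group_links, 0L)
  expect_equal(nm$path_length, 1)
  expect_equal(nm$global_efficiency, (15 * 20 * 19) / (300 * 299))

  # two complete components of 20: efficiency 19/39
  pop2 <- build_population(scenario_config(n_groups = 2, group_size = 20))
  expect_equal(network_metrics(pop2$network)$global_efficiency, 19 / 39)

  # random small networks against the BFS oracle
  set.seed(31)
  for (k in 1:10) {
    n_groups <- sample(2:5, 1)
    group <- rep(seq_len(n_groups), each = 5)
    n <- length(group)
    cross <- which(outer(group, group, "!=") & upper.tri(diag(n)), arr.ind = TRUE)
    picked <- cross[sample(nrow(cross), sample(0:4, 1)), , drop = FALSE]
    net <- make_network(group, data.frame(from = picked[, 1], to = picked[, 2],
                                          round_created = seq_len(nrow(picked))))
    nm <- network_metrics(net)
    adj <- network_adjacency(net)
    expect_equal(nm$path_length, oracle_path_length(adj))
    expect_equal(nm$global_efficiency, oracle_efficiency(adj))
    expect_equal(nm$between_group_links, nrow(picked))
    expect_gte(nm$global_efficiency, 0)
    expect_lte(nm$global_efficiency, 1)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(37)
  group <- rep(1:3, each = 5)
  net <- make_network(group)
  eff <- network_metrics(net)$global_efficiency
  cross <- which(outer(group, group, "!=") & upper.tri(diag(15)), arr.ind = TRUE)
  for (k in sample(nrow(cross), 8)) {
    net <- register_partner_link(net, cross[k, 1], cross[k, 2], round = k)
    eff_new <- network_metrics(net)$global_efficiency
    expect_gte(eff_new, eff - 1e-12)
    eff <- eff_new
  }
})

test_that("ego-network statistics match set-union enumeration", {
  pop <- build_population(scenario_config(n_groups = 2, group_size = 5))
  # all identical toolkits of size 8
  stats <- ego_network_stats(pop)
  expect_equal(stats$ego_tools, rep(8, 10))
  expect_equal(stats$own_frac, rep(1, 10))
  expect_equal(stats$pool_frac, rep(1, 10))
  expect_equal(stats$mean_jaccard, rep(0, 10))

  # hand-set toolkits plus one between-group link
  pop$toolkits <- c(list(c("A_1.1", "A_1.2"), c("A_1.2", "B_1.1"),
                         c("B_1.1", "B_1.2"), c("C_1.1"), c("C_1.1", "C_1.2")),
                    rep(list(c("D_1.1", "D_1.2")), 5))
  pop$network$between <- data.frame(from = 1L, to = 6L, round_created = 2L)
  stats <- ego_network_stats(pop)
  pool <- length(unique(unlist(pop$toolkits)))  # 8 distinct tools
  # agent 1 ego set: group 1 (agents 1-5) + agent 6
  ego1 <- unique(unlist(pop$toolkits[c(1:5, 6)]))
  expect_equal(stats$ego_tools[1], length(ego1))
  expect_equal(stats$own_frac[1], 2 / length(ego1))
  expect_equal(stats$pool_frac[1], length(ego1) / pool)
  expect_equal(stats$mean_jaccard[1],
               mean(vapply(c(2:5, 6), function(j)
                 oracle_jaccard(pop$toolkits[[1]], pop$toolkits[[j]]),
                 numeric(1))))
  # agent 10 has no between-group link: ego = own group only
  ego10 <- unique(unlist(pop$toolkits[6:10]))
  expect_equal(stats$ego_tools[10], length(ego10))
  expect_equal(stats$mean_jaccard[10], 0)

  # all-pairs variant on agent 1's ego set
  stats_ap <- ego_network_stats(pop, mode = "allpairs")
  kits1 <- pop$toolkits[c(1, 2:5, 6)]
  brute <- combn(6, 2, function(ix) oracle_jaccard(kits1[[ix[1]]], kits1[[ix[2]]]))
  expect_equal(stats_ap$mean_jaccard[1], mean(brute))
})

test_that("ledger summaries recount a real run by enumeration", {
  res <- run_simulation(scenario_config("ii", n_groups = 3, group_size = 10,
                                        rounds = 30), seed = 13)
  s <- ledger_summaries(res)
  ever <- union(initial_toolkit(), unique(res$ledger$creations$tool))
  expect_equal(s$tools_ever, length(ever))
  expect_equal(s$tools_final, length(unique(unlist(res$population$toolkits))))
  expect_equal(s$max_stage, max(parse_tools(ever)$stage))
  expect_equal(s$crossover_levels, s$max_stage - 1L)
  expect_equal(s$crossover_events,
               sum(res$ledger$creations$kind == "crossover"))
  mlf <- mean(vapply(res$population$toolkits,
                     function(t) mean(log(toolkit_fitness(t))), numeric(1)))
  expect_equal(s$mean_log_fitness, mlf)
})

test_that("metrics_record aggregates the per-agent and per-group views", {
  res <- run_simulation(scenario_config("iv", n_groups = 3, group_size = 10,
                                        rounds = 20), seed = 17)
  rec <- metrics_record(res)
  expect_equal(nrow(rec$agents), 30L)
  expect_equal(nrow(rec$groups), 3L)
  expect_equal(rec$summary[["mean_entropy"]], mean(rec$agents$entropy))
  expect_equal(rec$groups$mean_entropy[2],
               mean(rec$agents$entropy[rec$agents$group == 2]))
  expect_equal(rec$summary[["between_group_links"]],
               nrow(res$network$between))
  expect_true(all(c("agent_jaccard", "group_jaccard", "max_stage",
                    "ego_pool_frac") %in% names(rec$summary)))
})
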