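relation_fixture_lines <- c(
  "subject\tsubject_type\tobject\tobject_type\trelation_type\tsign\tsentence",
  "CRY2\tgene\tdepression\tconcept\tregulation\tpositive\tCRY2 up in depression.",
  "CRY2\tgene\tdepression\tconcept\tregulation\tpositive\tCRY2 up in depression.",
  "CRY2\tgene\tdepression\tconcept\tregulation\tpositive\tSecond independent sentence.",
  "valproic_acid\tdrug\tCRY2\tgene\texpression\tnegative\tVPA lowers CRY2.")

test_that("relation loading de-duplicates sentences and screens rows", {
  path <- write_tsv_fixture(relation_fixture_lines)
  rec <- load_relations(path)
  expect_equal(nrow(rec), 3)  # one exact duplicate dropped

  loop <- write_tsv_fixture(c(relation_fixture_lines[1],
    "CRY2\tgene\tCRY2\tgene\tregulation\tpositive\tself."))
  expect_warning(r2 <- load_relations(loop), "self-loop")
  expect_equal(nrow(r2), 0)

  empty <- write_tsv_fixture(relation_fixture_lines[1])
  expect_equal(nrow(load_relations(empty)), 0)

  badtype <- write_tsv_fixture(c(relation_fixture_lines[1],
    "A\tgene\tB\tmineral\tregulation\tpositive\tx."))
  expect_error(load_relations(badtype), "entity type in row 1")
  badrel <- write_tsv_fixture(c(relation_fixture_lines[1],
    "A\tgene\tB\tconcept\tfriendship\tpositive\tx."))
  expect_error(load_relations(badrel), "relation type in row 1")
})

test_that("confidence aggregation is a step function of sentence count", {
  path <- write_tsv_fixture(relation_fixture_lines)
  edges <- aggregate_confidence(load_relations(path))
  cry2 <- edges[edges$subject == "CRY2", ]
  expect_equal(cry2$s, 2)
  expect_equal(cry2$confidence_class, "medium")

  expect_equal(confidence_class(c(1, 2, 3, 4, 6)),
               c("low", "medium", "high", "high", "high"))
  # configurable high threshold (the stricter ">3" reading)
  expect_equal(confidence_class(3, high_threshold = 4), "medium")
  # adding a sentence never lowers the class
  lv <- c(low = 1, medium = 2, high = 3)
  expect_true(all(diff(lv[confidence_class(1:10)]) >= 0))
})

test_that("network construction keeps parallel signed edges and types", {
  rows <- rbind(
    relation_rows("g1", "gene", "c1", "concept"),
    relation_rows("g1", "gene", "c2", "concept"),
    relation_rows("d1", "drug", "g1", "gene", sign = "negative"))
  rows$sentence <- paste0(rows$sentence, seq_len(nrow(rows)))
  class(rows) <- c("cr_relations", "data.frame")
  net <- build_network(aggregate_confidence(rows))
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)

  # opposite-sign evidence between one pair survives as parallel edges
  opp <- relation_rows(c("d1", "d1"), c("drug", "drug"), c("g1", "g1"),
                       c("gene", "gene"), sign = "positive")
  opp$sign <- c("positive", "negative")
  opp$sentence <- c("up.", "down.")
  class(opp) <- c("cr_relations", "data.frame")
  net2 <- build_network(aggregate_confidence(opp))
  expect_equal(nrow(net2$edges), 2)

  empty <- aggregate_confidence(
    structure(data.frame(), class = c("cr_relations", "data.frame")))
  net3 <- build_network(empty)
  expect_equal(nrow(net3$nodes), 0)
})

test_that("hub ranking by distinct-neighbor degree with lexicographic ties", {
  star <- do.call(rbind, lapply(1:4, function(i)
    relation_rows("HUB", "gene", paste0("c", i), "concept")))
  star$sentence <- paste0(star$sentence, 1:4)
  class(star) <- c("cr_relations", "data.frame")
  net <- build_network(aggregate_confidence(star))
  hubs <- find_hubs(net)
  expect_equal(hubs$id[1], "HUB")
  expect_equal(hubs$degree[1], 4)
  expect_equal(hubs$id[-1], paste0("c", 1:4))  # all degree-1, lexicographic
  expect_equal(find_hubs(net, node_type = "gene")$id, "HUB")
})

test_that("drug ranking counts distinct covered signature genes", {
  rows <- rbind(
    relation_rows(rep("drugA", 3), rep("drug", 3), c("g1", "g2", "g3"),
                  rep("gene", 3)),
    relation_rows("drugB", "drug", "g1", "gene"),
    relation_rows("drugC", "drug", "c1", "concept"))
  rows$sentence <- paste0("s", seq_len(nrow(rows)), ".")
  class(rows) <- c("cr_relations", "data.frame")
  net <- build_network(aggregate_confidence(rows))
  sig <- c("g1", "g2", "g3")
  rk <- rank_drugs(net, sig)
  expect_equal(rk$drug, c("drugA", "drugB"))  # drugC has coverage 0
  expect_equal(rk$coverage, c(3, 1))
})

test_that("greedy combination covers genes and matches exhaustive search", {
  mk_net <- function(cov) {
    rows <- do.call(rbind, lapply(names(cov), function(d)
      relation_rows(rep(d, length(cov[[d]])), rep("drug", length(cov[[d]])),
                    cov[[d]], rep("gene", length(cov[[d]])))))
    rows$sentence <- paste0("s", seq_len(nrow(rows)), ".")
    class(rows) <- c("cr_relations", "data.frame")
    build_network(aggregate_confidence(rows))
  }
  # one drug covering everything -> singleton
  netA <- mk_net(list(drugA = c("g1", "g2"), drugB = "g1"))
  comboA <- select_drug_combination(netA, c("g1", "g2"))
  expect_equal(comboA$drugs, "drugA")
  # disjoint coverage -> both picked
  netB <- mk_net(list(drugA = c("g1", "g2"), drugB = "g3"))
  comboB <- select_drug_combination(netB, c("g1", "g2", "g3"))
  expect_setequal(comboB$drugs, c("drugA", "drugB"))
  # uncoverable genes reported
  comboC <- select_drug_combination(netB, c("g1", "g2", "g3", "gX"))
  expect_equal(comboC$uncovered, "gX")
  # max_drugs cap respected
  comboD <- select_drug_combination(netB, c("g1", "g2", "g3"), max_drugs = 1)
  expect_equal(length(comboD$drugs), 1)

  # random instances: greedy size vs exhaustive optimum (H(n) bound, and
  # exact equality asserted when they agree by construction below)
  set.seed(151)
  genes <- paste0("g", 1:6)
  for (rep in 1:10) {
    cov <- lapply(setNames(nm = paste0("drug", 1:4)), function(d)
      sample(genes, sample(1:4, 1)))
    net <- mk_net(cov)
    combo <- select_drug_combination(net, genes)
    opt <- oracle_min_cover_size(cov, genes)
    expect_lte(length(combo$drugs), ceiling(log(6) + 1) * max(opt, 1))
    coverable <- intersect(genes, unique(unlist(cov)))
    expect_setequal(combo$covered, coverable)
  }
})

test_that("edge list and GraphML exports round-trip / are well-formed", {
  rel <- simulate_relations(seed = 8, n_edges = 25)
  net <- build_network(aggregate_confidence(rel))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  doc <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(doc), "graphml")
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               nrow(net$edges))
})
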