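roles_fix <- c(FGFR3 = "oncogene", MTOR = "oncogene", TP53 = "TSG",
               RB1 = "TSG", NOTCH1 = "both")

test_that("functional scores follow the oncogene/TSG/undefined rule", {
  expect_equal(functional_score("FGFR3", roles_fix), 1)
  expect_equal(functional_score("TP53", roles_fix), -1)
  expect_true(is.na(functional_score("NOTCH1", roles_fix)))   # dual role
  expect_true(is.na(functional_score("UNKNOWN", roles_fix)))  # absent
})

test_that("aggregate scores average defined members only", {
  expect_equal(aggregate_score(c("FGFR3", "MTOR"), roles_fix)$score, 1)
  expect_equal(aggregate_score(c("FGFR3", "TP53"), roles_fix)$score, 0)
  agg <- aggregate_score(c("NOTCH1", "TP53"), roles_fix)
  expect_equal(agg$score, -1)
  expect_equal(agg$n_scored, 1)
  expect_true(is.na(aggregate_score("NOTCH1", roles_fix)$score))
})

mk_tab <- function(rows) {
  tab <- data.frame(protein_id = paste0("p", seq_len(nrow(rows))),
                    gene_symbol = rows$gene, condition = "drugX",
                    log2ratio = rows$lfc, p_value = rows$p,
                    q_value = rows$p * 2, n_perturbed = 3, n_control = 3,
                    response_class = rows$class, stringsAsFactors = FALSE)
  class(tab) <- c("response_table", "data.frame")
  tab
}

mk_module_summary <- function(genes, lfc) {
  members <- data.frame(module_id = 1L, gene = genes, role = "seed",
                        log2ratio = lfc, stringsAsFactors = FALSE)
  modules <- data.frame(module_id = 1L, size = length(genes),
                        n_measured = sum(!is.na(lfc)),
                        mean_log2ratio = mean(lfc, na.rm = TRUE),
                        direction = if (mean(lfc, na.rm = TRUE) > 0) "up"
                                    else "down",
                        stringsAsFactors = FALSE)
  structure(list(modules = modules, members = members),
            class = "module_summary")
}

test_that("mechanism flagging follows the score/direction rule", {
  tab <- mk_tab(data.frame(gene = c("FGFR3", "TP53"), lfc = c(0.87, 0.6),
                           p = c(0.002, 0.01),
                           class = c("strong_up", "strong_up")))
  # up-regulated oncogene-rich module (mirrors a +0.99 two-gene module)
  ms_up <- mk_module_summary(c("FGFR3", "MTOR"), c(0.99, 0.99))
  mech <- flag_mechanisms("drugX", list(fi = ms_up), table = tab,
                          roles = roles_fix)
  mod <- mech[mech$evidence_kind == "netbox_module", ]
  expect_true(mod$flagged)
  expect_equal(mod$mean_log2ratio, 0.99)

  # individual strong_up oncogene flagged; strong_up TSG not
  ind <- mech[mech$evidence_kind == "individual_protein", ]
  expect_true(ind$flagged[ind$entity == "FGFR3"])
  expect_false(ind$flagged[ind$entity == "TP53"])

  # up-regulated TSG-rich module is not flagged
  ms_bad <- mk_module_summary(c("TP53", "RB1"), c(0.9, 0.9))
  mech2 <- flag_mechanisms("drugX", list(fi = ms_bad), table = tab,
                           roles = roles_fix)
  expect_false(mech2$flagged[mech2$evidence_kind == "netbox_module"])

  # |mean log2ratio| below 0.5 blocks the module flag
  ms_weak <- mk_module_summary(c("FGFR3", "MTOR"), c(0.3, 0.3))
  mech3 <- flag_mechanisms("drugX", list(fi = ms_weak), table = tab,
                           roles = roles_fix)
  expect_false(mech3$flagged[mech3$evidence_kind == "netbox_module"])
})

test_that("the flag rule is antisymmetric in (score, direction)", {
  tab <- mk_tab(data.frame(gene = "X", lfc = 0, p = 1, class = "constant"))
  flag_of <- function(role, dir) {
    ms <- mk_module_summary(c("g1", "g2"), c(0.9, 0.9) * dir)
    mech <- flag_mechanisms("drugX", list(fi = ms), table = tab,
                            roles = c(g1 = role, g2 = role))
    mech$flagged[mech$evidence_kind == "netbox_module"]
  }
  # negating both score and direction preserves the flag ...
  expect_true(flag_of("oncogene", 1))
  expect_true(flag_of("TSG", -1))
  # ... negating exactly one flips it to FALSE
  expect_false(flag_of("oncogene", -1))
  expect_false(flag_of("TSG", 1))
})

test_that("GSEA processes qualify at q < 0.25 with the same rule", {
  tab <- mk_tab(data.frame(gene = c("FGFR3", "MTOR", "TP53"),
                           lfc = c(1, 0.8, 0), p = c(0.001, 0.002, 0.9),
                           class = c("strong_up", "strong_up", "constant")))
  gsc <- make_collection(list(PROC = c("FGFR3", "MTOR")))
  gres <- data.frame(set_id = "PROC", size = 2, es = 0.9, nes = 2,
                     p_value = 0.001, q_value = 0.01, leading_edge = "FGFR3",
                     stringsAsFactors = FALSE)
  mech <- flag_mechanisms("drugX", list(), gres, gsc, tab, roles_fix)
  proc <- mech[mech$evidence_kind == "gsea_process", ]
  expect_true(proc$flagged)
  gres$q_value <- 0.5  # not significant -> no process row
  mech2 <- flag_mechanisms("drugX", list(), gres, gsc, tab, roles_fix)
  expect_false("gsea_process" %in% mech2$evidence_kind)
})

test_that("candidates are ranked by clinical stage then evidence", {
  tab <- mk_tab(data.frame(gene = c("CDK6", "EGFR"), lfc = c(0.931, 1.19),
                           p = c(0.00455, 0.0101),
                           class = c("strong_up", "strong_up")))
  roles <- c(CDK6 = "oncogene", EGFR = "oncogene")
  mech <- flag_mechanisms("drugX", list(), table = tab, roles = roles)
  drugs <- data.frame(drug = c("palbociclib", "erlotinib", "experimentalX"),
                      target = c("CDK6", "EGFR", "CDK6"),
                      clinical_stage_rank = c(1L, 1L, 3L),
                      stringsAsFactors = FALSE)
  cand <- nominate(mech, drugs, "MEKi")
  expect_equal(cand$tested_drug[1], "MEKi")
  # both rank-1 partners precede the rank-3 partner
  expect_equal(sort(cand$partner[cand$clinical_stage == 1])[1], "erlotinib")
  expect_lt(which(cand$partner == "palbociclib")[1],
            which(cand$partner == "experimentalX")[1])
  # rank-1 with larger evidence magnitude (EGFR lfc 1.19) comes first
  expect_equal(cand$partner[1], "erlotinib")

  # deterministic total order: repeated call identical
  expect_identical(nominate(mech, drugs, "MEKi"), cand)
})

test_that("a flagged mechanism without any inhibitor is still reported", {
  tab <- mk_tab(data.frame(gene = "UGCG", lfc = 1.2, p = 0.001,
                           class = "strong_up"))
  mech <- flag_mechanisms("drugX", list(), table = tab,
                          roles = c(UGCG = "oncogene"))
  drugs <- data.frame(drug = "unrelated", target = "SOMETHING",
                      clinical_stage_rank = 2L, stringsAsFactors = FALSE)
  cand <- nominate(mech, drugs, "MEKi")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$partner, "")
  expect_match(cand$note, "no inhibitor available")
  expect_error(nominate(mech, drugs[0, ], "MEKi"), "empty drug annotation")
})
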