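mk_raw_event <- function(gene, clade_id, taxa, evidence = "supported_conflict") {
  ev <- lgtrates:::empty_events()
  ev[1, c("event_id", "evidence", "ambiguity")] <-
    list(paste0(gene, ".", clade_id), evidence, "firm")
  ev$dup_family[1] <- NA_character_
  ev$age_lo[1] <- NA_real_; ev$age_hi[1] <- NA_real_
  ev$genes[[1]] <- gene
  ev$taxa[[1]] <- sort(taxa)
  ev$copies[[1]] <- paste0(gene, ".", clade_id)
  ev
}

empty_linkage <- function() {
  linkage_table(data.frame(taxon = character(), copy_a = character(),
                           copy_b = character(), gap_orfs = integer()))
}

test_that("propose_events confirms gains against assessments", {
  ref <- random_dated_tree(8)
  taxa <- ref$phylo$tip.label
  # trait everywhere, congruent: nothing to report
  a_all <- data.frame(gene = "g", clade = "c", verdict = "congruent",
                      max_conflict_support = NA_real_,
                      n_shared_taxa = 8L, stringsAsFactors = FALSE)
  a_all$taxa <- list(sort(taxa))
  expect_equal(nrow(propose_events(NULL, a_all, ref)), 0L)

  gains <- data.frame(gene = "g")
  gains$taxa <- list(sort(taxa[1:3]))
  # supported conflict clade nested in the gain: one event
  a1 <- a_all; a1$verdict <- "supported_conflict"; a1$taxa <- list(sort(taxa[1:3]))
  a1$n_shared_taxa <- 3L
  ev <- propose_events(gains, a1, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$evidence, "supported_conflict")
  # congruent but restricted, with a gain: taxonomic_restriction evidence
  a2 <- a1; a2$verdict <- "congruent"
  expect_equal(propose_events(gains, a2, ref)$evidence, "taxonomic_restriction")
  # and configurable off
  expect_equal(nrow(propose_events(gains, a2, ref,
                                   allow_taxonomic_restriction = FALSE)), 0L)
  # gain with no assessed clade at all: warned, ASR-only tier
  expect_warning(ev3 <- propose_events(gains, NULL, ref), "ASR-only")
  expect_equal(ev3$evidence, "asr_gain")
  expect_equal(unname(event_counts(ev3)["min"]), 0)
})

test_that("collapse_linked merges identical-recipient linked events", {
  halo <- c("Halobacterium", "Halorubrum", "Haloferax")
  ev <- rbind(mk_raw_event("CoxA1", "h", halo), mk_raw_event("CoxB1", "h", halo))
  link <- linkage_table(data.frame(taxon = "Halobacterium",
                                   copy_a = "CoxA1.h", copy_b = "CoxB1.h",
                                   gap_orfs = 0L))
  es <- collapse_linked(ev, link)
  expect_equal(nrow(es$events), 1L)
  expect_setequal(es$events$genes[[1]], c("CoxA1", "CoxB1"))

  # gap of one ORF still merges at the default max_gap_orfs = 1 ...
  fp <- c("Ferroplasma", "Picrophilus")
  ev2 <- rbind(mk_raw_event("CoxAC", "e", fp), mk_raw_event("CoxB", "e", fp))
  link2 <- linkage_table(data.frame(taxon = "Picrophilus",
                                    copy_a = "CoxAC.e", copy_b = "CoxB.e",
                                    gap_orfs = 1L))
  expect_equal(nrow(collapse_linked(ev2, link2)$events), 1L)
  # ... but not with a stricter gap limit
  expect_equal(nrow(collapse_linked(ev2, link2, max_gap_orfs = 0)$events), 2L)

  # different recipients never merge, linked or not
  ev3 <- rbind(mk_raw_event("A", "x", c("t1", "t2")),
               mk_raw_event("B", "y", c("t1", "t3")))
  link3 <- linkage_table(data.frame(taxon = "t1", copy_a = "A.x",
                                    copy_b = "B.y", gap_orfs = 0L))
  expect_equal(nrow(collapse_linked(ev3, link3)$events), 2L)

  # empty linkage: identity
  expect_equal(nrow(collapse_linked(ev, empty_linkage())$events), 2L)
})

test_that("collapse_linked is idempotent, transitive and order-invariant", {
  taxa <- c("t1", "t2")
  ev <- rbind(mk_raw_event("A", "c", taxa), mk_raw_event("B", "c", taxa),
              mk_raw_event("C", "c", taxa), mk_raw_event("D", "z", c("t3")))
  link <- linkage_table(data.frame(
    taxon = c("t1", "t1"), copy_a = c("A.c", "B.c"),
    copy_b = c("B.c", "C.c"), gap_orfs = c(0L, 0L)))
  es <- collapse_linked(ev, link)
  expect_equal(nrow(es$events), 2L)              # {A,B,C} transitive + {D}
  expect_setequal(es$events$genes[[1]], c("A", "B", "C"))
  # idempotent
  es2 <- collapse_linked(es$events, link)
  expect_equal(nrow(es2$events), 2L)
  # permutation invariant (as a set of gene-group/taxa signatures)
  sig <- function(e) sort(vapply(seq_len(nrow(e$events)), function(i)
    paste(paste(e$events$genes[[i]], collapse = "+"),
          paste(e$events$taxa[[i]], collapse = ","), sep = "@"), ""))
  for (k in 1:5) {
    perm <- ev[sample(nrow(ev)), , drop = FALSE]
    expect_equal(sig(collapse_linked(perm, link)), sig(es))
  }
})

test_that("duplication flags produce the reported min/max counts", {
  sulf <- c("Sulfolobus_tokodaii", "Metallosphaera")
  ev <- rbind(mk_raw_event("SoxM", "s", sulf), mk_raw_event("SoxB", "s", sulf),
              mk_raw_event("DoxB", "s", sulf), mk_raw_event("FoxA", "s", sulf))
  es <- collapse_linked(ev, empty_linkage())
  flags <- data.frame(gene = c("SoxB", "DoxB", "FoxA"),
                      clade = "s", family = "fam1",
                      flagged = c(FALSE, TRUE, TRUE))
  es2 <- apply_duplication_flags(es, flags)
  expect_equal(unname(event_counts(es2)), c(2, 4))

  # no flags: min == max
  expect_equal(unname(event_counts(es)), c(4, 4))

  # an entirely-flagged family still contributes one event to the minimum
  flags_all <- data.frame(gene = c("SoxM", "SoxB", "DoxB", "FoxA"),
                          clade = "s", family = "famX", flagged = TRUE)
  es3 <- apply_duplication_flags(es, flags_all)
  expect_equal(unname(event_counts(es3)), c(1, 4))

  expect_error(apply_duplication_flags(es, data.frame(
    gene = "Nope", clade = "s", family = "f", flagged = TRUE)),
    "matches no event")
})

test_that("date_events assigns stem age intervals on the chronogram", {
  fx <- load_archaea_fixture()
  ev <- rbind(
    mk_raw_event("SOR", "s1", c("Ferroplasma", "Picrophilus")),
    mk_raw_event("X", "r", fx$ref_tree$clade_labels$Crenarchaeota))
  es <- collapse_linked(ev, empty_linkage())
  dated <- date_events(es, fx$ref_tree)
  e1 <- dated$events[dated$events$event_id == "E001", ]
  expect_equal(e1$age_lo, 0.8)     # Ferroplasma-Picrophilus crown
  expect_equal(e1$age_hi, 1.5)     # Thermoplasmatales crown (its parent)
  # an event on a root child has the root age as its upper bound
  e2 <- dated$events[dated$events$event_id == "E002", ]
  expect_equal(e2$age_hi, 3.5)

  # non-monophyletic recipient is an error naming the taxa
  bad <- collapse_linked(
    mk_raw_event("Y", "b", c("Halobacterium", "Sulfolobus")), empty_linkage())
  expect_error(date_events(bad, fx$ref_tree), "not monophyletic")
})

test_that("simulated insertion times fall inside the reported interval", {
  inside <- 0; total <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_taxa = 16, n_gains = 1, seed = s)
    tr <- simulate_reference_tree(cfg)
    hist <- simulate_gene_history(tr, cfg)
    if (!nrow(hist$gains)) next
    ev <- mk_raw_event("g1", "c", hist$gains$taxa[[1]])
    dated <- date_events(collapse_linked(ev, empty_linkage()), tr)
    total <- total + 1
    t_true <- hist$gains$time[1]
    if (t_true >= dated$events$age_lo[1] - 1e-9 &&
        t_true <= dated$events$age_hi[1] + 1e-9) inside <- inside + 1
  }
  expect_gte(inside / total, 0.95)
})

test_that("transfer rates reproduce the printed rounding", {
  expect_equal(transfer_rate(11, 3.5), 3.1)
  expect_equal(transfer_rate(8, 3.5), 2.3)
  expect_equal(transfer_rate(0, 3.5), 0.0)
  expect_equal(transfer_rate(2, 3.5), 0.6)
  expect_equal(transfer_rate(3, 3.5), 0.9)    # 0.857 rounds up
  expect_equal(transfer_rate(22, 3.5), 6.3)   # 6.285...
  expect_error(transfer_rate(1, 0), "positive")
  expect_error(transfer_rate(-1, 3.5), "negative")
  # round-half-away-from-zero, not banker's rounding
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})
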