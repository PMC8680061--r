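mtab <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(doc_id = r[[1L]], type_label = r[[2L]],
               char_start = as.integer(r[[3L]]), char_end = as.integer(r[[4L]]),
               stringsAsFactors = FALSE)
  }))
}

# Brute-force one-to-one matching over all (gold, pred) pairs.
oracle_counts <- function(gold, pred, excluded = "UNCLEAR") {
  gold <- gold[!(gold$type_label %in% excluded), , drop = FALSE]
  pred <- pred[!(pred$type_label %in% excluded), , drop = FALSE]
  taken <- rep(FALSE, nrow(gold))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gold))) {
      if (!taken[j] &&
          pred$doc_id[i] == gold$doc_id[j] &&
          pred$type_label[i] == gold$type_label[j] &&
          pred$char_start[i] == gold$char_start[j] &&
          pred$char_end[i] == gold$char_end[j]) {
        taken[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  c(TP = tp, FP = nrow(pred) - tp, FN = nrow(gold) - tp)
}

test_that("micro P/R/F1 reproduce the published worked examples to 4 decimals", {
  # headline overall row: P 0.9225, R 0.9050 -> F1 0.9137
  expect_equal(round(f1_score(0.9225, 0.9050), 4), 0.9137)
  # one-pass guideline overall: P 0.9135, R 0.9121 -> F1 0.9128
  expect_equal(round(f1_score(0.9135, 0.9121), 4), 0.9128)
  # per-type rows: NORMALIZABLES 0.9428/0.9322 -> 0.9375;
  # PROTEINAS 0.8994/0.8847 -> 0.892
  expect_equal(round(f1_score(0.9428, 0.9322), 4), 0.9375)
  expect_equal(round(f1_score(0.8994, 0.8847), 3), 0.892)
  # rare-type row with perfect precision and 10% recall -> 0.1818
  expect_equal(round(f1_score(1.0, 0.1), 4), 0.1818)
  # harmonic mean of equal precision and recall is that value
  for (p in c(0.1, 0.5, 0.9137)) expect_equal(f1_score(p, p), p)
})

test_that("strict matching requires identical (doc, type, start, end)", {
  gold <- mtab(list("d1", "PROTEINAS", 0, 5), list("d1", "NORMALIZABLES", 10, 18),
               list("d2", "PROTEINAS", 3, 9))
  rep0 <- per_type_report(gold, gold)
  expect_equal(unname(rep0$counts$overall), c(3L, 0L, 0L))
  expect_equal(rep0$f1, 1)

  # one character off on either boundary is a miss under exact match
  pred <- gold
  pred$char_start[1L] <- 1L
  rep1 <- per_type_report(gold, pred)
  expect_equal(unname(rep1$counts$overall), c(2L, 1L, 1L))

  # wrong type at the right offsets is also a miss
  pred2 <- gold
  pred2$type_label[1L] <- "NORMALIZABLES"
  rep2 <- per_type_report(gold, pred2)
  expect_equal(unname(rep2$counts$overall), c(2L, 1L, 1L))

  # duplicate identical predictions: one TP, extras FP
  pred3 <- rbind(gold, gold[1L, ])
  rep3 <- per_type_report(gold, pred3)
  expect_equal(unname(rep3$counts$overall), c(3L, 1L, 0L))
})

test_that("UNCLEAR is excluded from both sides at scoring time", {
  gold <- mtab(list("d1", "PROTEINAS", 0, 5), list("d1", "UNCLEAR", 10, 14))
  pred <- mtab(list("d1", "PROTEINAS", 0, 5), list("d1", "UNCLEAR", 20, 24))
  rep_ex <- per_type_report(gold, pred)
  expect_equal(unname(rep_ex$counts$overall), c(1L, 0L, 0L))
  expect_false("UNCLEAR" %in% rep_ex$per_type$type_label)
  # the same predictions re-scored without exclusion count the UNCLEAR miss
  rep_in <- per_type_report(gold, pred, excluded_types = character())
  expect_equal(unname(rep_in$counts$overall), c(1L, 1L, 1L))
})

test_that("counts equal the brute-force all-pairs oracle on perturbed corpora", {
  set.seed(19)
  for (rep in 1:5) {
    gold <- random_mention_table(500L)
    pred <- gold
    flip <- sample(500L, 150L)   # ~30% perturbed
    mode <- sample(3L, length(flip), replace = TRUE)
    pred$char_start[flip[mode == 1L]] <- pred$char_start[flip[mode == 1L]] + 1L
    pred$type_label[flip[mode == 2L]] <-
      sample(entity_types(), sum(mode == 2L), replace = TRUE)
    pred$doc_id[flip[mode == 3L]] <- "dXX"
    got <- strict_match_counts(gold, pred)
    expect_equal(got$overall, oracle_counts(gold, pred))
    # per-type counts sum to the overall micro counts
    expect_equal(sum(got$per_type$TP), unname(got$overall["TP"]))
    expect_equal(sum(got$per_type$FP), unname(got$overall["FP"]))
    expect_equal(sum(got$per_type$FN), unname(got$overall["FN"]))
  }
})

test_that("swapping gold and predictions swaps precision and recall exactly", {
  set.seed(23)
  gold <- random_mention_table(200L)
  pred <- random_mention_table(180L)
  a <- per_type_report(gold, pred)
  b <- per_type_report(pred, gold)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
  expect_equal(a$f1, b$f1)
})

test_that("adding a false positive lowers precision and F1 but not recall", {
  gold <- mtab(list("d1", "PROTEINAS", 0, 5), list("d1", "PROTEINAS", 8, 12))
  pred <- gold
  r0 <- per_type_report(gold, pred)
  pred_fp <- rbind(pred, mtab(list("d1", "PROTEINAS", 50, 60)))
  r1 <- per_type_report(gold, pred_fp)
  expect_lt(r1$precision, r0$precision)
  expect_lt(r1$f1, r0$f1)
  expect_equal(r1$recall, r0$recall)
})

test_that("zero denominators follow the report-zero convention", {
  gold <- mtab(list("d1", "PROTEINAS", 0, 5))
  none <- mtab(list("d1", "PROTEINAS", 7, 9))[0, ]
  r <- per_type_report(gold, none)
  expect_equal(r$precision, 0)
  expect_equal(r$recall, 0)
  expect_equal(r$f1, 0)
  # a type with predictions but no gold mirrors the convention on recall
  r2 <- per_type_report(none, gold)
  expect_equal(r2$recall, 0)
  # F1 lies between P and R whenever P + R > 0
  set.seed(31)
  gold3 <- random_mention_table(80L)
  pred3 <- rbind(gold3[sample(80L, 40L), ], random_mention_table(30L))
  r3 <- per_type_report(gold3, pred3)
  expect_gte(r3$f1, min(r3$precision, r3$recall))
  expect_lte(r3$f1, max(r3$precision, r3$recall))
})

test_that("a single-type corpus yields a per-type row equal to the overall row", {
  gold <- mtab(list("d1", "PROTEINAS", 0, 5), list("d2", "PROTEINAS", 3, 9))
  pred <- mtab(list("d1", "PROTEINAS", 0, 5), list("d2", "PROTEINAS", 4, 9))
  r <- per_type_report(gold, pred)
  row <- r$per_type[r$per_type$type_label == "PROTEINAS", ]
  expect_equal(row$precision, r$precision)
  expect_equal(row$recall, r$recall)
  expect_equal(row$f1, r$f1)
})

test_that("reports export TSV and JSON with 4-decimal rounding and an OVERALL row", {
  gold <- mtab(list("d1", "PROTEINAS", 0, 5), list("d1", "NORMALIZABLES", 8, 12),
               list("d1", "NORMALIZABLES", 20, 24))
  pred <- mtab(list("d1", "PROTEINAS", 0, 5), list("d1", "NORMALIZABLES", 8, 12))
  r <- per_type_report(gold, pred)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, tsv = tsv, json = js)
  tab <- read.delim(tsv)
  expect_equal(names(tab), c("type", "TP", "FP", "FN", "P", "R", "F1"))
  expect_equal(tail(tab$type, 1L), "OVERALL")
  expect_equal(tail(tab$F1, 1L), round(f1_score(1, 2 / 3), 4))
  jtab <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jtab$F1, tab$F1)
})
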