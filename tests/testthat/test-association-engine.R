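test_that("score and one-tailed Fisher p match hand-derived tables", {
    st <- scoreAndTest(3, 0, 0, 7)
    expect_equal(st$score, 1)
    expect_equal(st$p, 1 / choose(10, 3), tolerance = 1e-12)

    st <- scoreAndTest(0, 5, 5, 5)
    expect_equal(st$score, 0)
    expect_equal(st$p, 1)

    st <- scoreAndTest(4, 1, 2, 8)
    expect_equal(st$score, 0.64)
    expect_equal(st$p, bruteUpperTailP(4, 1, 2, 8), tolerance = 1e-12)
    expect_equal(st$p, 0.0470, tolerance = 1e-3)
})

test_that("engine p equals the enumeration oracle on random tables", {
    set.seed(31)
    for (i in 1:200) {
        cg <- sample(0:12, 1); cb <- sample(0:12, 1)
        tg <- sample(0:12, 1); tb <- sample(0:12, 1)
        if (cg + cb < 1 || tg + tb < 1) next
        st <- scoreAndTest(cg, cb, tg, tb)
        expect_equal(st$p, bruteUpperTailP(cg, cb, tg, tb), tolerance = 1e-12)
        expect_equal(st$score, expectedScore(cg, cb, tg, tb), tolerance = 1e-12)
    }
})

test_that("score is bounded and p is monotone in case enrichment", {
    set.seed(32)
    for (i in 1:50) {
        cg <- sample(0:8, 1); cb <- sample(0:8, 1)
        tg <- sample(0:8, 1); tb <- sample(0:8, 1)
        if (cg + cb < 1 || tg + tb < 1) next
        st <- scoreAndTest(cg, cb, tg, tb)
        expect_gte(st$score, 0); expect_lte(st$score, 1)
        expect_gt(st$p, 0); expect_lte(st$p, 1)
        expect_identical(st$score == 1, cb == 0 && tg == 0)
    }
    # with all margins fixed, moving one good response from controls to
    # cases never increases p and never decreases score
    for (i in 1:50) {
        cg <- sample(1:6, 1); cb <- sample(1:6, 1)
        tg <- sample(1:6, 1); tb <- sample(1:6, 1)
        a <- scoreAndTest(cg, cb, tg, tb)
        b <- scoreAndTest(cg + 1, cb - 1, tg - 1, tb + 1)
        expect_lte(b$p, a$p + 1e-15)
        expect_gte(b$score, a$score - 1e-15)
    }
})

test_that("case selection honours combine modes, filters and guards", {
    rec <- data.frame(
        cell_line = c("L1", "L2", "L2", "L3", "L4"),
        tissue = c("breast", "breast", "breast", "lung", "lung"),
        gene = c("geneA", "geneA", "geneB", "geneB", "geneC"),
        variant_classification = c("Missense_Mutation", "Missense_Mutation",
                                   "Silent", "Missense_Mutation",
                                   "Missense_Mutation"),
        stringsAsFactors = FALSE)
    mt <- MutationTable(rec, cellLineUniverse = c("L1", "L2", "L3", "L4", "L5"))

    s <- selectCaseLines(mt, MutationQuery(genes = "geneA"))
    expect_setequal(caseLines(s), c("L1", "L2"))
    expect_setequal(controlLines(s), c("L3", "L4", "L5"))

    s <- selectCaseLines(mt, MutationQuery(genes = c("geneA", "geneB"),
                                           combineMode = "all_of"))
    expect_identical(caseLines(s), "L2")

    s <- selectCaseLines(mt, MutationQuery(genes = c("geneA", "geneB"),
                                           combineMode = "any_of"))
    expect_setequal(caseLines(s), c("L1", "L2", "L3"))

    # variant-class filter removes the Silent call backing L2's geneB
    s <- selectCaseLines(mt, MutationQuery(genes = "geneB",
                                           variantClasses = "Missense_Mutation"))
    expect_identical(caseLines(s), "L3")

    # tissue filter restricts cases and controls
    s <- selectCaseLines(mt, MutationQuery(genes = "geneA", tissues = "breast"))
    expect_setequal(caseLines(s), c("L1", "L2"))
    expect_length(controlLines(s), 0L)

    expect_warning(
        s <- selectCaseLines(mt, MutationQuery(genes = c("geneA", "nope"),
                                               combineMode = "any_of")),
        "nope")
    expect_setequal(caseLines(s), c("L1", "L2"))
    expect_error(
        suppressWarnings(selectCaseLines(mt, MutationQuery(genes = "nope"))),
        "nope", class = "pm_empty_error")
})

test_that("gene-to-drug ranks perfect separation first and applies guards", {
    calls <- makeCallsFixture(goodLines = sprintf("G%d", 1:3),
                              badLines = sprintf("B%d", 1:7))
    split <- CaseControlSplit(sprintf("G%d", 1:3), sprintf("B%d", 1:7))
    res <- geneToDrug(calls, split)
    expect_identical(res$compound_id[1], "DRUG")
    expect_equal(res$score[1], 1)
    expect_equal(res$p_value[1], bruteUpperTailP(3, 0, 0, 7), tolerance = 1e-12)
    expect_true(res$significant[1])
    expect_false(any(res$significant[-1]))
    expect_true(all(diff(res$p_value) >= 0))

    # a compound untested on every case line is dropped, with a log line
    cm <- matrix(rnorm(40), 4, 10,
                 dimnames = list(sprintf("C%d", 1:4),
                                 c(sprintf("G%d", 1:3), sprintf("B%d", 1:7))))
    cm[1, 1:3] <- NA
    calls2 <- callResponses(NormalizedResponse(cm))
    expect_message(res2 <- geneToDrug(calls2, split, minCtrl = 2L),
                   "skipped 1 compound")
    expect_false("C1" %in% res2$compound_id)
})

test_that("family enrichment matches the hypergeometric oracle", {
    df <- data.frame(
        compound_id = sprintf("NSC-%02d", 1:10),
        family = c("F", "F", "F", rep("G", 7)),
        score = c(0.9, 0.8, 0.7, 0.95, 0.85, rep(0.1, 5)),
        p_value = rep(0.01, 10), stringsAsFactors = FALSE)
    fam <- enrichFamilies(df, scoreThreshold = 0.6)
    fRow <- fam[fam$family == "F", ]
    expect_identical(fRow$n_family_sig, 3L)
    expect_identical(fRow$n_background_sig, 5L)
    expect_equal(fRow$p_value, choose(5, 3) / choose(10, 3), tolerance = 1e-12)
    expect_equal(fRow$p_value, 10 / 120, tolerance = 1e-12)
    # anti-enriched family
    gRow <- fam[fam$family == "G", ]
    expect_gte(gRow$p_value, 0.5)

    # single family covering everything is uninformative
    df$family <- "F"
    fam1 <- enrichFamilies(df)
    expect_equal(fam1$p_value, 1)

    # nothing passes the threshold -> warning, all p = 1
    df$score <- 0.1
    expect_warning(fam0 <- enrichFamilies(df), "threshold")
    expect_true(all(fam0$p_value == 1))
})

test_that("drug-to-gene scores mutation carriage across response groups", {
    good <- c("L1", "L2", "L3")
    bad <- sprintf("L%d", 4:10)
    calls <- makeCallsFixture(good, bad)
    rec <- data.frame(cell_line = c("L1", "L2", "L6"), tissue = "breast",
                      gene = "MUT", variant_classification = "Missense_Mutation",
                      stringsAsFactors = FALSE)
    mt <- MutationTable(rec, cellLineUniverse = c(good, bad))
    v <- drugToGene(calls, "DRUG", mt)
    expect_identical(nrow(v), 1L)
    expect_equal(v$score_sens, (2 / 3) * (6 / 7), tolerance = 1e-12)
    expect_equal(v$p_sens, 22 / 120, tolerance = 1e-12)
    expect_equal(v$p_sens, bruteUpperTailP(2, 1, 1, 6), tolerance = 1e-12)
    expect_identical(v$bubble_size, 3L)

    # perfect separation: carried by every good line, no bad line
    rec2 <- data.frame(cell_line = good, gene = "PERF",
                       variant_classification = "Missense_Mutation",
                       stringsAsFactors = FALSE)
    mt2 <- MutationTable(rbind(rec[, names(rec2)], rec2),
                         cellLineUniverse = c(good, bad))
    v2 <- drugToGene(calls, "DRUG", mt2)
    perf <- v2[v2$gene == "PERF", ]
    expect_equal(perf$score_sens, 1)
    expect_equal(perf$score_res, 0)
    expect_true(perf$sensitivity)
    expect_false(perf$resistance)

    # a key carried by no line in either group is absent
    mt3 <- MutationTable(
        rbind(rec[, names(rec2)],
              data.frame(cell_line = "L99", gene = "GHOST",
                         variant_classification = "Missense_Mutation")),
        cellLineUniverse = c(good, bad, "L99"))
    v3 <- drugToGene(calls, "DRUG", mt3)
    expect_false("GHOST" %in% v3$gene)
})

test_that("swapping response groups exchanges sensitivity and resistance", {
    good <- sprintf("G%d", 1:4)
    bad <- sprintf("B%d", 1:8)
    rec <- data.frame(
        cell_line = c("G1", "G2", "B1", "B2", "B3", "G3"),
        gene = rep(c("M1", "M2"), each = 3),
        variant_classification = "Missense_Mutation", stringsAsFactors = FALSE)
    mt <- MutationTable(rec, cellLineUniverse = c(good, bad))
    v1 <- drugToGene(makeCallsFixture(good, bad), "DRUG", mt)
    v2 <- drugToGene(makeCallsFixture(bad, good), "DRUG", mt)
    v2 <- v2[match(v1$gene, v2$gene), ]
    expect_equal(v1$score_sens, v2$score_res, tolerance = 1e-12)
    expect_equal(v1$p_sens, v2$p_res, tolerance = 1e-12)
    expect_equal(v1$score_res, v2$score_sens, tolerance = 1e-12)
    expect_equal(v1$p_res, v2$p_sens, tolerance = 1e-12)
})

test_that("duplicate variant calls count once per line but keep bubble size", {
    good <- c("L1", "L2", "L3")
    bad <- sprintf("L%d", 4:10)
    rec <- data.frame(cell_line = c("L1", "L1", "L2", "L6"),
                      gene = "MUT", variant_classification = "Missense_Mutation",
                      position = c(100L, 100L, 100L, 100L),
                      stringsAsFactors = FALSE)
    mt <- MutationTable(rec, cellLineUniverse = c(good, bad))
    v <- drugToGene(makeCallsFixture(good, bad), "DRUG", mt)
    # L1's duplicated call is deduplicated before counting carriers
    expect_identical(v$n_good_bearing, 2L)
    # ... but the raw call count drives the bubble size
    expect_identical(v$bubble_size, 4L)
})

test_that("distribution summaries cover significant records and conserve counts", {
    good <- c("L1", "L2", "L3")
    bad <- sprintf("L%d", 4:10)
    calls <- makeCallsFixture(good, bad)
    rec <- data.frame(cell_line = good, tissue = c("breast", "breast", "lung"),
                      gene = "PERF", variant_classification = "Missense_Mutation",
                      stringsAsFactors = FALSE)
    mt <- MutationTable(rec, cellLineUniverse = c(good, bad))
    v <- drugToGene(calls, "DRUG", mt)
    d <- summarizeDistributions(v, mt, cellLines = c(good, bad))
    total <- sum(v$bubble_size[v$sensitivity | v$resistance])
    expect_identical(sum(d$cellLines$count), total)
    expect_identical(sum(d$tissues$count), total)
    expect_identical(sum(d$variantClasses$count), total)
    expect_identical(d$tissues$count[d$tissues$label == "breast"], 2L)

    # zero significant records -> three empty tables
    vNone <- v; vNone$sensitivity <- FALSE; vNone$resistance <- FALSE
    d0 <- summarizeDistributions(vNone, mt)
    expect_identical(vapply(d0, nrow, integer(1L)),
                     c(cellLines = 0L, tissues = 0L, variantClasses = 0L))
})
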