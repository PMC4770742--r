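# In-code fixtures shared across test files.

writeTempLines <- function(lines) {
    path <- tempfile(fileext = ".tsv")
    writeLines(lines, path)
    path
}

tinyResponseFile <- function() {
    writeTempLines(c("compound_id\tA\tB",
                     "NSC-1\t6\t5",
                     "NSC-2\t7\t",
                     "NSC-3\t6.5\t6"))
}

tinyMutationFile <- function() {
    writeTempLines(c(
        paste("Tumor_Sample_Barcode", "Hugo_Symbol", "tissue",
              "Variant_Classification", "Variant_Type", "Chromosome",
              "Start_position", "dbSNP_RS", sep = "\t"),
        "L1\tTP53\tbreast\tMissense_Mutation\tSNP\t17\t7579472\trs0000001",
        "L1\tPTEN\tbreast\tNonsense_Mutation\tSNP\t10\t89692905\t",
        "L2\tTP53\tlung\tMissense_Mutation\tSNP\t17\t7578406\trs0000002",
        "L2\tKRAS\tlung\tMissense_Mutation\tSNP\t12\t25398284\trs0000003"))
}

# A ResponseCalls object where compound `targetId` has prescribed
# good/bad response lines; filler compounds respond "bad" everywhere.
makeCallsFixture <- function(goodLines, badLines, targetId = "DRUG",
                             nFiller = 19L) {
    lines <- c(goodLines, badLines)
    m <- matrix(0, nFiller + 1L, length(lines),
                dimnames = list(c(targetId, sprintf("FILL-%02d", seq_len(nFiller))),
                                lines))
    m[targetId, goodLines] <- -10
    callResponses(NormalizedResponse(m), minCompounds = 3L)
}

smallPlantedSpec <- function(seed = 7L, effect = -3, nCarriers = 8L,
                             nCompounds = 200L,
                             plantedId = sprintf("NSC-%05d", nCompounds %/% 2)) {
    PanelSpec(nCompounds = nCompounds, nCellLines = 60L,
              plantedEffects = data.frame(compound_id = plantedId,
                                          gene = "MUT1",
                                          effect_log2 = effect,
                                          n_carriers = nCarriers,
                                          stringsAsFactors = FALSE),
              seed = seed)
}
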