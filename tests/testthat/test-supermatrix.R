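test_that("marker selection enforces full complement and paralog budget", {
    mat <- rbind(
        single = rep(1L, 10),                 # one copy everywhere
        missing = c(0L, rep(1L, 9)),          # absent in one genome
        heavy = c(6L, rep(1L, 9)))            # extras = 5
    colnames(mat) <- paste0("g", 1:10)
    expect_true("single" %in% selectMarkers(mat))
    expect_false("missing" %in% selectMarkers(mat, maxExtraParalogs = 100))
    expect_false("heavy" %in% selectMarkers(mat, maxExtraParalogs = 4))
    expect_true("heavy" %in% selectMarkers(mat, maxExtraParalogs = 5))
    ## per-genome reading: 5 extra copies in one genome
    expect_false("heavy" %in% selectMarkers(mat, maxExtraParalogs = 4,
                                            perGenome = TRUE))
    expect_true("heavy" %in% selectMarkers(mat, maxExtraParalogs = 5,
                                           perGenome = TRUE))
    ## monotone in the budget
    for (k in 0:5)
        expect_true(all(selectMarkers(mat, maxExtraParalogs = k) %in%
                        selectMarkers(mat, maxExtraParalogs = k + 1L)))
})

test_that("consensus takes the majority residue with alphabetical ties", {
    one <- Biostrings::AAStringSet(c(x = "ACDEF"))
    expect_identical(consensusSequence(one), "ACDEF")
    msa <- Biostrings::AAStringSet(c(x = "AAW", y = "AWW", z = "AAA"))
    ## columns: {A,A,A}=A, {A,W,A}=A, {W,W,A}=W
    expect_identical(consensusSequence(msa), "AAW")
    tie <- Biostrings::AAStringSet(c(x = "AW", y = "WA"))
    expect_identical(consensusSequence(tie), "AA")
    gaps <- Biostrings::AAStringSet(c(x = "A-", y = "A-"))
    expect_identical(consensusSequence(gaps), "A-")
})

test_that("the index ortholog maximises consensus BLOSUM62 score", {
    ## paralog q2 differs from consensus at 10 of 12 positions
    msa <- Biostrings::AAStringSet(c(
        a = "AAAAAAAAAAAA", b = "AAAAAAAAAAAA",
        q1 = "AAAAAAAAAAAA", q2 = "WWWWWWWWWWAA"))
    gm <- c(a = "g1", b = "g2", q1 = "g3", q2 = "g3")
    expect_identical(selectIndexOrtholog(msa, "g3", gm), "q1")
    expect_identical(selectIndexOrtholog(msa, "g1", gm), "a")
    ## exact tie: lexicographically smaller id
    msa2 <- Biostrings::AAStringSet(c(z2 = "AAAA", z1 = "AAAA",
                                      o = "AAAA"))
    gm2 <- c(z2 = "g1", z1 = "g1", o = "g2")
    expect_identical(selectIndexOrtholog(msa2, "g1", gm2), "z1")
    expect_error(selectIndexOrtholog(msa2, "g9", gm2), "absent")
})

test_that("column homogeneity matches hand computation", {
    expect_equal(columnHomogeneity(c("A", "A", "A")), 1.0)
    ## mean(4/4, 4/4, -3/4, -3/4) = 0.125 with s(A,A)=4, s(A,W)=-3
    expect_equal(columnHomogeneity(c("A", "A", "W", "W"), "A"), 0.125)
    expect_equal(columnHomogeneity(c("-", "-")), 0)
    expect_error(columnHomogeneity(character(0)), "non-empty")
})

test_that("column filtering applies the gap and homogeneity gates", {
    ## col1: 3 gaps of 4 (0.75 > 0.667) -> removed
    ## col2: 2 gaps (0.5), both residues consensus -> kept
    ## col3: A,A,W,W -> homogeneity 0.125 >= 0.05 -> kept
    msa <- Biostrings::AAStringSet(c(r1 = "-AA", r2 = "-AA",
                                     r3 = "--W", r4 = "A-W"))
    filt <- filterColumns(msa)
    expect_equal(attr(filt, "removed"), 1L)
    expect_equal(attr(filt, "kept"), 2L)
    expect_identical(as.character(filt),
                     c(r1 = "AA", r2 = "AA", r3 = "-W", r4 = "-W"))
    ## idempotent
    again <- filterColumns(filt)
    expect_identical(as.character(again), as.character(filt))
    ## gap-free identical MSA unchanged
    clean <- Biostrings::AAStringSet(c(a = "AAA", b = "AAA"))
    expect_identical(as.character(filterColumns(clean)),
                     as.character(clean))
    ## everything removed -> empty MSA with a warning
    allgap <- Biostrings::AAStringSet(c(a = "--", b = "--"))
    expect_warning(out <- filterColumns(allgap), "all columns")
    expect_equal(unique(Biostrings::width(out)), 0L)
})

test_that("concatenation tracks partitions and ignores genome order", {
    msas <- list(
        C1 = Biostrings::AAStringSet(c(p1 = strrep("A", 10),
                                       p2 = strrep("C", 10))),
        C2 = Biostrings::AAStringSet(c(q1 = strrep("D", 15),
                                       q2 = strrep("E", 15))))
    im <- list(C1 = list(gA = "p1", gB = "p2"),
               C2 = list(gA = "q1", gB = "q2"))
    sm <- concatenateMarkers(c("C2", "C1"), msas, im, c("gA", "gB"))
    w <- Biostrings::width(superAlignment(sm))
    expect_equal(unique(w), 25L)
    p <- partitions(sm)
    expect_equal(p$cluster_id, c("C1", "C2"))
    expect_equal(p$start, c(0L, 10L))
    expect_equal(p$end, c(10L, 25L))
    ## permuting the genome order permutes rows, not content
    sm2 <- concatenateMarkers(c("C1", "C2"), msas, im, c("gB", "gA"))
    expect_identical(as.character(superAlignment(sm)[["gA"]]),
                     as.character(superAlignment(sm2)[["gA"]]))
    ## a missing index ortholog is named in the error
    im2 <- im; im2$C1$gB <- NULL
    expect_error(concatenateMarkers(c("C1", "C2"), msas, im2,
                                    c("gA", "gB")), "C1.*gB")
})

test_that("zero-divergence single-copy data yields an invariant supermatrix", {
    sim <- simulateGenomeSet(simulationConfig(
        nGenomes = 5, nFamilies = 8, gainRate = 0, lossRate = 0,
        dupRate = 0, rootPresenceProb = 1,
        withinFamilyDivergence = 0, seed = 6))
    fm <- familyMembership(sim$truth)
    cs <- ClusterSet(clusters = lapply(split(names(fm), fm), sort),
                     genomeMap = genomeIds(sim$genomes))
    cs <- attachSequences(cs, sim$genomes)
    res <- buildSupermatrix(cs)
    aln <- superAlignment(res$supermatrix)
    expect_equal(length(res$markers), 8L)
    expect_length(unique(as.character(aln)), 1L)   # zero variable columns
    ## row degapped length bounded by the summed ortholog lengths
    expect_lte(unique(Biostrings::width(aln)), 8L * 120L)
})
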