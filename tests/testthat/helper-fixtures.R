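# shared fixtures and independent oracles

# brute-force residue-set intersection (oracle for interval sweep)
bruteIntersection <- function(a, b) {
    length(intersect(residueSet(a), residueSet(b)))
}

# random SegmentList under the current RNG
randomSegmentList <- function(maxResidue = 200L, maxSegments = 5L) {
    k <- sample(maxSegments, 1L)
    starts <- sort(sample(maxResidue, k))
    ends <- starts + sample(0:30, k, replace = TRUE)
    SegmentList(starts, ends)
}

# tiny ProteinModel with uniform PAE and linear coordinates
toyModel <- function(n = 20, pae_value = 3, proteinId = "TOY",
                     plddt = NULL, sse = NULL) {
    pae <- matrix(pae_value, n, n)
    diag(pae) <- 0
    coords <- cbind(3.8 * seq_len(n), 0, 0)
    ProteinModel(proteinId, coords, pae, plddt = plddt, sse = sse)
}

# one-perturbation ted chopping for a truth, with a fixed mode
tedFromTruth <- function(truth, spec) {
    perturbAnnotation(truthDomains(truth), spec)
}
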