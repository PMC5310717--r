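# Shared fixtures built in code.

# panel where every locus is fixed: species A always allele 100,
# species B always allele 97
fixedPanel <- function(n_loci = 3) {
  new("LocusPanel",
      loci = paste0("L", seq_len(n_loci)),
      alleles = rep(list(c(97L, 100L)), n_loci),
      freqA = rep(list(c(0, 1)), n_loci),
      freqB = rep(list(c(1, 0)), n_loci))
}

# a panel from explicit frequency vectors (single shared allele list)
panelFrom <- function(freqA, freqB, alleles = NULL) {
  k <- length(freqA[[1]])
  if (is.null(alleles)) alleles <- as.integer(seq(100, by = 2,
                                                  length.out = k))
  new("LocusPanel", loci = paste0("L", seq_along(freqA)),
      alleles = rep(list(alleles), length(freqA)),
      freqA = freqA, freqB = freqB)
}

# build a MultilocusGenotypes from a list of per-individual genotype
# lists: list(c(a, b), c(a, b), ...) one pair per locus
genoFrom <- function(..., loci = NULL) {
  rows <- list(...)
  L <- length(rows[[1]]) / 2
  a1 <- matrix(unlist(lapply(rows, function(r) r[seq(1, 2 * L, 2)])),
               ncol = L, byrow = TRUE)
  a2 <- matrix(unlist(lapply(rows, function(r) r[seq(2, 2 * L, 2)])),
               ncol = L, byrow = TRUE)
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  newGenotypes(a1, a2, loci)
}

# replicate-read rows for consensus tests
readRow <- function(sample_id, locus, a1, a2 = NA, replicate = 1,
                    multiplex = 1, date = "2012-05-22") {
  data.frame(sample_id = sample_id, date = date, multiplex = multiplex,
             replicate = replicate, locus = locus,
             allele1 = as.integer(a1), allele2 = as.integer(a2))
}

extfile <- function(name) system.file("extdata", name,
                                      package = "guanotype")
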