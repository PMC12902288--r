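# Programmatic fixtures: all test data are built in code at test time.

# a genotype_matrix straight from components (bypasses VCF I/O)
make_gm <- function(geno, pops, contig = "chr1", pos = seq_len(nrow(geno)),
                    qual = rep(60, nrow(geno)), contig_len = max(pos) + 10) {
  samples <- data.frame(id = paste0("s", seq_len(ncol(geno))), pop = pops,
                        stringsAsFactors = FALSE)
  sites <- data.frame(contig = rep(contig, length.out = nrow(geno)),
                      pos = pos, qual = qual, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  cts <- unique(sites$contig)
  contigs <- data.frame(name = cts,
                        length = rep(contig_len, length.out = length(cts)),
                        stringsAsFactors = FALSE)
  colnames(geno) <- samples$id
  introflow:::new_genotype_matrix(geno, sites, samples, contigs)
}

# an allele_freq_table straight from a frequency matrix (counts all equal)
make_freqs <- function(p, roles = setNames(colnames(p), colnames(p)),
                       contig = "chr1", pos = seq_len(nrow(p)), n = 20,
                       polarized = TRUE) {
  structure(list(sites = data.frame(contig = rep(contig, length.out = nrow(p)),
                                    pos = pos, stringsAsFactors = FALSE),
                 p = p, n = matrix(n, nrow(p), ncol(p),
                                   dimnames = list(NULL, colnames(p))),
                 roles = roles, polarized = polarized),
            class = "allele_freq_table")
}

# the constructed 5-record toy VCF of the filter example: one low-QUAL
# site, one high-missingness site, one low-MAF site, two passing sites
write_filter_fixture_vcf <- function(dir = tempdir()) {
  vcf <- file.path(dir, "filter_fixture.vcf")
  popmap <- file.path(dir, "filter_fixture.popmap.tsv")
  ids <- paste0("s", 1:10)
  gts <- list(
    qual_fail = rep(c("0/0", "0/1"), 5),
    miss_fail = c(rep("./.", 3), rep("0/1", 7)),
    maf_fail  = c("0/1", rep("0/0", 9)),        # MAF = 1/20 = 0.05 exactly
    pass1     = rep(c("0/1", "1/1"), 5),
    pass2     = c(rep("0/0", 5), rep("1/1", 5)))
  quals <- c(25, 60, 60, 60, 60)
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=100000>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO",
                     "FORMAT", ids), collapse = "\t"))
  for (i in seq_along(gts))
    lines <- c(lines, paste(c("chr1", i * 100, ".", "A", "T", quals[i],
                              "PASS", ".", "GT", gts[[i]]), collapse = "\t"))
  writeLines(lines, vcf)
  writeLines(paste(ids, "pop1", sep = "\t"), popmap)
  list(vcf = vcf, popmap = popmap)
}
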