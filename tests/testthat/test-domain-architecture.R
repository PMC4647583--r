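# Architecture parsing, gene classification, module decomposition,
# tandem clustering and A-domain specificity codes.

test_that("architecture strings parse in order and reject unknown tokens", {
  a <- parseArchitecture("AM-PP-KS-AT", "g1", 957)
  expect_identical(domains(a), c("AM", "PP", "KS", "AT"))
  expect_identical(geneId(a), "g1")
  expect_identical(domains(parseArchitecture("KS")), "KS")
  # case-insensitive, whitespace tolerated, HxxPF accepted
  expect_identical(domains(parseArchitecture("c - HxxPF - a")),
                   c("C", "HXXPF", "A"))
  expect_error(parseArchitecture("KS-ZZ"), "'ZZ' at token 2")
})

test_that("classification is total and matches the survey rules", {
  expect_equal(classifyGene("KS"), "SINGLE_KS")
  expect_equal(classifyGene("AM-PP-KS-AT"), "MULTI_PKS")
  expect_equal(classifyGene("C-A-PP-KS-AT-PP"), "HYBRID_NRPS_PKS")
  expect_equal(classifyGene("C-HXXPF-A"), "NON_PKS")  # no KS present
  expect_equal(classifyGene("AM-KS-KR-PP-KS-DH-KR-PP-KS"), "MULTI_PKS")
  # string and coordinate inputs with the same code list classify identically
  co <- architectureFromCoords(
    data.frame(domain_code = c("AM", "PP", "KS", "AT"),
               start_aa = c(1, 120, 260, 700),
               end_aa = c(100, 200, 600, 850)), "g1")
  expect_equal(classifyGene(co), classifyGene("AM-PP-KS-AT"))
})

test_that("the 25 survey architecture strings yield 15 single-KS genes and the hybrid", {
  tab <- ksGeneSurvey()
  expect_equal(nrow(tab), 25L)
  cls <- vapply(tab$domain_string, classifyGene, "", USE.NAMES = FALSE)
  expect_equal(sum(cls == "SINGLE_KS"), 15L)
  expect_equal(cls[tab$gene_id == "symbB1.v1.2.012436.t1"], "HYBRID_NRPS_PKS")
})

test_that("module decomposition follows the anchoring rules and partitions the architecture", {
  m <- decomposeModules("C-A-PP-KS-AT-PP-KS-KR-PP-C-A-PP-TE")
  expect_equal(nrow(m), 4L)
  expect_equal(m$kind, c("NRPS", "PKS", "PKS", "NRPS"))
  expect_equal(m$members[4], "C-A-PP-TE")  # TE joins the final module

  expect_equal(decomposeModules("KS")$kind, "PKS")
  expect_equal(decomposeModules("C-HXXPF-A")$kind, "NRPS_LIKE")

  # no anchor at all -> flagged loading-only module
  lo <- decomposeModules("AM-PP-TE")
  expect_equal(lo$kind, "LOADING_ONLY")
  expect_true(lo$loading)

  # pre-anchor domains form a loading module whose kind follows the anchor
  ld <- decomposeModules("AM-PP-KS-AT")
  expect_equal(ld$kind[1], "PKS")
  expect_true(ld$loading[1])

  # the reconstructed hybrid: 8 modules, 3 NRPS-type, 5 PKS
  tab <- ksGeneSurvey()
  hyb <- decomposeModules(tab$domain_string[tab$gene_id ==
                                              "symbB1.v1.2.012436.t1"])
  expect_equal(nrow(hyb), 8L)
  expect_equal(sum(hyb$kind %in% c("NRPS", "NRPS_LIKE")), 3L)
  expect_equal(sum(hyb$kind == "PKS"), 5L)
  expect_equal(hyb$kind[6], "NRPS_LIKE")
})

test_that("module members concatenate back to the architecture on random inputs", {
  set.seed(77)
  for (rep in 1:200) {
    arch <- randomArchitecture()
    m <- decomposeModules(arch)
    rebuilt <- paste(m$members, collapse = "-")
    expect_identical(rebuilt, toupper(arch))
  }
})

test_that("domain counting matches string structure", {
  expect_equal(countDomains("AM-KS-KR-PP-KS-DH-KR-PP-KS", "KS"), 3L)
  expect_equal(countDomains("KS", "AT"), 0L)
  expect_error(countDomains("KS", "ZZ"), "unknown domain code")
  set.seed(9)
  for (rep in 1:50) {
    arch <- parseArchitecture(randomArchitecture())
    total <- sum(vapply(unique(domains(arch)),
                        function(cd) countDomains(arch, cd), integer(1)))
    expect_equal(total, length(arch))
  }
})

test_that("tandem clusters recover the survey's scaffold groupings", {
  tab <- ksGeneSurvey()
  tab$gene_class <- vapply(tab$domain_string, classifyGene, "",
                           USE.NAMES = FALSE)
  cl <- findTandemClusters(tab)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$scaffold, c("1186.1", "514.1"))
  g1186 <- strsplit(cl$gene_ids[cl$scaffold == "1186.1"], ";")[[1]]
  expect_setequal(g1186, c("symbB1.v1.2.015790.t1", "symbB1.v1.2.015788.t2",
                           "symbB1.v1.2.015789.t1"))
  g514 <- strsplit(cl$gene_ids[cl$scaffold == "514.1"], ";")[[1]]
  expect_setequal(g514, c("symbB1.v1.2.008781.t1", "symbB1.v1.2.008782.t1"))

  # all genes on distinct scaffolds -> no clusters
  solo <- data.frame(gene_id = c("a", "b"), scaffold = c("s1", "s2"))
  expect_equal(nrow(findTandemClusters(solo)), 0L)
})

test_that("tandem clustering agrees with a brute-force grouping oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    tab <- data.frame(gene_id = paste0("g", seq_len(n)),
                      scaffold = paste0("s", sample(1:10, n, replace = TRUE)))
    got <- findTandemClusters(tab)
    want <- Filter(function(x) length(x) >= 2,
                   split(tab$gene_id, tab$scaffold))
    expect_equal(nrow(got), length(want))
    for (sc in names(want))
      expect_setequal(strsplit(got$gene_ids[got$scaffold == sc], ";")[[1]],
                      want[[sc]])
  }
})

test_that("A-domain specificity codes survive padding, gaps, and planted mutations", {
  ref <- aDomainReference()
  # identity: the reference's own pocket residues
  expect_equal(extractADomainCode(ref$sequence)$code, "DAWTIAAI")

  # leading/trailing padding of the query leaves the code unchanged
  set.seed(12)
  pad <- paste0(randomProtein(25), ref$sequence, randomProtein(25))
  expect_equal(extractADomainCode(pad)$code, "DAWTIAAI")

  # insertion upstream of the pocket positions is absorbed by the gaps
  ins <- paste0(substr(ref$sequence, 1, 100), randomProtein(10),
                substr(ref$sequence, 101, nchar(ref$sequence)))
  expect_equal(extractADomainCode(ins)$code, "DAWTIAAI")

  # pocket residues mutated to known letters are read back exactly
  mut <- strsplit(ref$sequence, "")[[1]]
  mut[ref$pocket_positions] <- strsplit("DLFNLSLI", "")[[1]]
  expect_equal(extractADomainCode(paste(mut, collapse = ""))$code, "DLFNLSLI")

  # insufficient reference coverage is refused with a diagnostic
  short <- substr(ref$sequence, 1, 80)
  r <- extractADomainCode(short)
  expect_true(r$refused)
  expect_true(is.na(r$code))
  expect_match(attr(r$refused, "reason"), "coverage|covers")
})
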