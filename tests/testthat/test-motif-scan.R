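# Degenerate motif compilation, scanning and active-site verification.

test_that("motif compilation follows the pattern grammar and rejects malformed input", {
  m <- compileMotif("GHSLG")
  expect_s4_class(m, "CompiledMotif")
  expect_length(m, 5L)
  expect_true(all(vapply(m@elements, function(e) e$kind == "literal", TRUE)))

  # one position per letter, wildcard, or bracket set
  expect_length(compileMotif("GxG[AG]"), 4L)
  expect_length(compileMotif("HxxxGxxxx"), 9L)

  # wildcard-only matcher accepts any single residue
  for (ch in c("A", "W", "X"))
    expect_equal(nrow(scanMotif(ch, compileMotif("x"))), 1L)

  # errors carry the offending position
  expect_error(compileMotif("GH[AG"), "position 3")
  expect_error(compileMotif("GhSLG"), "position 2")
  expect_error(compileMotif("G1SLG"), "position 2")
  expect_error(compileMotif(""), "empty")
  expect_error(compileMotif("G[]A"), "empty bracket")
})

test_that("bracket-set matching agrees with brute-force enumeration over a small alphabet", {
  # all 256 4-mers over {A, C, G, T} (valid protein letters) vs GxG[AG]
  alpha <- c("A", "C", "G", "T")
  words <- apply(expand.grid(alpha, alpha, alpha, alpha,
                             stringsAsFactors = FALSE), 1, paste,
                 collapse = "")
  m <- compileMotif("GxG[AG]")
  got <- vapply(words, function(w) nrow(scanMotif(w, m)) == 1L, TRUE)
  want <- vapply(words, function(w) {
    ch <- strsplit(w, "")[[1]]
    ch[1] == "G" && ch[3] == "G" && ch[4] %in% c("A", "G")
  }, TRUE)
  expect_identical(unname(got), unname(want))
  expect_true(got[["GAGA"]] && got[["GCGG"]] && !got[["GAGT"]])
})

test_that("nucleotide IUPAC degeneracy compiles to strict sets", {
  m <- compileMotif("DCCG", alphabet = "nucleotide")
  expect_equal(m@elements[[1]]$kind, "set")
  expect_setequal(m@elements[[1]]$letters, c("A", "G", "T"))
  expect_equal(nrow(scanMotif("TCCG", m)), 1L)
  expect_equal(nrow(scanMotif("CCCG", m)), 0L)
  # degenerate positions never consume the substitution budget
  expect_equal(nrow(scanMotif("CCCG", m, maxSubstitutions = 2L)), 0L)
})

test_that("scanning reports substitution counts, overlaps, and normalizes case", {
  hit <- scanMotif("AAGHSLGAA", "GHSLG")
  expect_equal(hit$start, 3L)
  expect_equal(hit$substitutions, 0L)
  expect_equal(hit$matched_span, "GHSLG")

  expect_equal(nrow(scanMotif("AAGHSAGAA", "GHSLG", 0L)), 0L)
  hit1 <- scanMotif("AAGHSAGAA", "GHSLG", 1L)
  expect_equal(hit1$start, 3L)
  expect_equal(hit1$substitutions, 1L)

  # overlapping hits all reported, ascending starts
  hits <- scanMotif("AAAAA", "AA")
  expect_equal(hits$start, 1:4)

  expect_equal(nrow(scanMotif("", "GHSLG")), 0L)
  expect_warning(h <- scanMotif("aaghslgaa", "GHSLG"), "lowercase")
  expect_equal(h$start, 3L)

  # ambiguity residue X never matches a literal
  expect_equal(nrow(scanMotif("AAGXSLGAA", "GHSLG", 0L)), 0L)
  expect_equal(scanMotif("AAGXSLGAA", "GHSLG", 1L)$substitutions, 1L)
})

test_that("scanner output equals the brute-force oracle on random sequences", {
  motifs <- pksMotifs()
  set.seed(101)
  for (rep in 1:12) {
    s <- randomProtein(sample(50:500, 1))
    for (m in motifs) {
      for (k in 0:2) {
        got <- scanMotif(s, m, k)
        want <- naiveMotifScan(s, m@pattern, k)
        expect_identical(got$start, as.integer(want$start))
        expect_identical(got$substitutions, as.integer(want$substitutions))
      }
    }
  }
})

test_that("hit sets grow monotonically with the substitution budget", {
  set.seed(55)
  m <- compileMotif("DTACSS")
  for (rep in 1:10) {
    s <- randomProtein(300)
    prev <- integer()
    for (k in 0:3) {
      starts <- scanMotif(s, m, k)$start
      expect_true(all(prev %in% starts))
      prev <- starts
    }
  }
})

test_that("KS active-site verification checks Cys, His and Lys near DTACSS", {
  ok <- paste0(strrep("A", 15), "DTACSS", strrep("G", 20), "H",
               strrep("G", 30), "K", strrep("A", 10))
  r <- verifyKSActiveSite(ok)
  expect_true(r$cys_ok && r$his_ok && r$lys_ok && r$overall)
  expect_equal(r$motif_hit$start, 16L)

  # Cys mutated: motif still found with 1 substitution, but cys_ok fails
  noCys <- sub("DTACSS", "DTAGSS", ok, fixed = TRUE)
  r2 <- verifyKSActiveSite(noCys, maxSubstitutions = 1L)
  expect_false(r2$cys_ok)
  expect_false(r2$overall)
  expect_equal(r2$motif_hit$substitutions, 1L)

  # missing downstream Lys
  noLys <- paste0(strrep("A", 15), "DTACSS", strrep("G", 20), "H",
                  strrep("G", 300))
  r3 <- verifyKSActiveSite(noLys, lysWindow = 250L)
  expect_true(r3$his_ok)
  expect_false(r3$lys_ok && r3$overall)

  # empty / motif-free sequence
  r4 <- verifyKSActiveSite("")
  expect_null(r4$motif_hit)
  expect_false(r4$overall)
})

test_that("the active-site report ignores residues beyond the search windows", {
  base <- paste0(strrep("A", 10), "DTACSS", strrep("G", 20), "H",
                 strrep("G", 30), "K")
  r1 <- verifyKSActiveSite(base)
  r2 <- verifyKSActiveSite(paste0(base, strrep("W", 400)))
  expect_identical(r1[c("cys_ok", "his_ok", "lys_ok", "overall")],
                   r2[c("cys_ok", "his_ok", "lys_ok", "overall")])
})

test_that("N-terminal signature classification labels GYLG and its variants", {
  expect_equal(classifyNTermSignature("MAEAELGYLGKKAAAA")$variant_label, "GYLG")
  expect_equal(classifyNTermSignature("MAEAELDYLGKKAAAA")$variant_label, "DYLG")
  expect_equal(classifyNTermSignature("MAEAELEYLGKKAAAA")$variant_label, "EYLG")
  expect_equal(classifyNTermSignature("MAEAELGYMGKKAAAA")$variant_label, "GYMG")
  r <- classifyNTermSignature("MAEAELGYLGKK")
  expect_equal(r$position, 3L)
  expect_equal(r$core_tetrapeptide, "GYLG")

  # no signature above threshold
  none <- classifyNTermSignature(strrep("M", 60))
  expect_equal(none$variant_label, "OTHER(----)")
  expect_true(is.na(none$position))

  # an unknown tetrapeptide with strong E-x-E context is reported literally
  oth <- classifyNTermSignature("MAEAELWWLGKKAAAA")
  expect_equal(oth$variant_label, "OTHER(WWLG)")

  # search restricted to the N-terminal window
  far <- paste0(strrep("A", 200), "EAEAGYLG")
  expect_equal(classifyNTermSignature(far)$variant_label, "OTHER(----)")
})

test_that("DH signature reports the catalytic His and downstream proline flag", {
  s <- paste0(strrep("A", 5), "HAAAGAAAA", strrep("A", 10), "P",
              strrep("A", 5))
  r <- verifyDHSite(s)
  expect_true(r$his_ok)
  expect_true(r$pro_downstream)
  noP <- paste0(strrep("A", 5), "HAAAGAAAA", strrep("A", 40))
  expect_false(verifyDHSite(noP)$pro_downstream)
})
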