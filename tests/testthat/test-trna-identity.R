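pser <- trna_pser()
catalog <- identity_catalog()
hosts <- catalog[c("GlyRS", "SerRS", "ThrRS")]

test_that("element matching covers bases, pairs and structural predicates", {
  c2g71 <- identity_element("base_pair", 2, 71, "C:G")
  expect_true(element_matches(pser, c2g71))
  evl <- identity_element("structural", feature = "extended_variable_loop",
                          threshold = 10)
  expect_false(element_matches(pser, evl))
  u73 <- identity_element("base", 73, required = "U")
  expect_true(element_matches(pser, u73))
  # positions absent from the numbering error out
  partial <- trna_seq("partial",
                      setNames(c("G", "C", "U", "A", "C", "U"),
                               c(1, 72, 34, 35, 36, 73)))
  expect_error(element_matches(partial, c2g71), "absent")
})

test_that("profile overlap returns exactly the matched subset", {
  gly_matched <- overlap_elements(pser, catalog$GlyRS)
  expect_setequal(gly_matched, c("G1:C72", "C2:G71", "U73"))
  # subset property and monotonicity under element removal
  all_labels <- vapply(catalog$GlyRS$elements, `[[`, "", "label")
  expect_true(all(gly_matched %in% all_labels))
  smaller <- recognition_profile("GlyRS", catalog$GlyRS$elements[1:2])
  expect_true(all(overlap_elements(pser, smaller) %in% gly_matched))
  # no-match profile yields an empty overlap
  alien <- recognition_profile("X",
    list(identity_element("base", 73, required = "G")))
  expect_length(overlap_elements(pser, alien), 0)
})

test_that("host screening flags GlyRS and ThrRS but never SerRS", {
  scr <- screen_host_recognition(pser, hosts)
  expect_setequal(scr$aars[scr$flagged], c("GlyRS", "ThrRS"))
  expect_equal(scr$n_matched[scr$aars == "GlyRS"], 3)
  expect_false(scr$flagged[scr$aars == "SerRS"])
  expect_false(scr$structural_ok[scr$aars == "SerRS"])

  # even a permissive threshold cannot overcome the structural veto
  lax <- lapply(hosts, function(p) {
    p$flag_threshold <- 1
    p
  })
  scr1 <- screen_host_recognition(pser, lax)
  expect_false(scr1$flagged[scr1$aars == "SerRS"])

  # a sequence with no matches anywhere flags nothing
  blank <- trna_seq("blank",
                    setNames(c("A", "A", "U", "U", "C", "U", "A", "A"),
                             c(1, 2, 71, 72, 34, 35, 36, 73)))
  scr0 <- screen_host_recognition(blank, hosts["GlyRS"])
  expect_false(any(scr0$flagged))
  expect_equal(scr0$n_matched, 0)
})

test_that("flipping C2:G71 removes the shared element but keeps the cognate set", {
  opt <- flip_base_pair(pser, c(2, 71))
  expect_equal(opt$bases[["2"]], "G")
  expect_equal(opt$bases[["71"]], "C")
  scr_before <- screen_host_recognition(pser, hosts)
  scr_after <- screen_host_recognition(opt, hosts)
  for (a in c("GlyRS", "ThrRS")) {
    expect_equal(scr_after$n_matched[scr_after$aars == a],
                 scr_before$n_matched[scr_before$aars == a] - 1)
    expect_false(scr_after$flagged[scr_after$aars == a])
  }
  expect_setequal(overlap_elements(opt, catalog$pSerRS), c("G1:C72", "U73"))

  # involution: flipping twice restores the sequence
  back <- flip_base_pair(opt, c(2, 71))
  expect_identical(back$bases, pser$bases)
  expect_identical(back$name, pser$name)
  # untouched positions stay untouched
  moved <- c("2", "71")
  expect_identical(opt$bases[setdiff(names(opt$bases), moved)],
                   pser$bases[setdiff(names(pser$bases), moved)])
  expect_error(flip_base_pair(pser, c(10, 25)), "not an acceptor-stem pair")
})

test_that("mutation proposal finds the acceptor-stem flip and nothing cognate-breaking", {
  cand <- propose_orthogonalizing_mutations(pser, catalog$pSerRS, hosts)
  expect_true(any(grepl("flip\\(2,71\\)", cand$mutation)))
  expect_false(any(grepl("flip\\(1,72\\)", cand$mutation)))
  expect_false(any(cand$type == "discriminator"))  # would break U73
  expect_true(all(cand$reduction > 0))

  # every proposal keeps the cognate profile fully matched when applied
  flip_rows <- cand[cand$type == "pair_flip", ]
  for (i in seq_len(nrow(flip_rows))) {
    pr <- as.integer(regmatches(flip_rows$mutation[i],
      regexec("flip\\((\\d+),(\\d+)\\)", flip_rows$mutation[i]))[[1]][2:3])
    mut <- flip_base_pair(pser, pr)
    expect_length(overlap_elements(mut, catalog$pSerRS),
                  length(catalog$pSerRS$elements))
  }

  # an already-orthogonal sequence proposes nothing
  opt <- flip_base_pair(pser, c(2, 71))
  blank_hosts <- list(recognition_profile("Y",
    list(identity_element("base", 73, required = "C"))))
  none <- propose_orthogonalizing_mutations(opt, catalog$pSerRS, blank_hosts)
  expect_equal(nrow(none), 0)
})

test_that("the constructor enforces the acceptor-stem invariants", {
  expect_error(trna_seq("bad", setNames(c("G", "G", "C", "U", "A", "U"),
                                        c(1, 72, 34, 35, 36, 73))),
               "not complementary")
  expect_warning(trna_seq("wobble", setNames(c("G", "U", "C", "U", "A", "U"),
                                             c(1, 72, 34, 35, 36, 73))),
                 "wobble")
  expect_error(trna_seq("nodisc", setNames(c("G", "C", "C", "U", "A"),
                                           c(1, 72, 34, 35, 36))),
               "discriminator")
  expect_equal(pser$var_loop_len, 5)
})

test_that("tRNA FASTA writing matches the position order", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "pser.fa")
  write_trna_fasta(pser, f)
  lines <- readLines(f)
  expect_equal(lines[1], ">tRNA-pSer")
  expect_equal(nchar(lines[2]), length(pser$bases))
  expect_equal(substr(lines[2], 1, 2), "GC")   # G1, C2
  expect_equal(substr(lines[2], 73, 76), "UCCA")  # discriminator + CCA
})
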