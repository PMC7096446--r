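test_that("FASTA records are parsed, normalized, and round-trip", {
  f <- write_temp_fasta(c(">P1", "KKDDE"))
  recs <- read_fasta(f)
  expect_equal(recs$id, "P1")
  expect_equal(recs$sequence, "KKDDE")

  # case normalization and trailing stop-mark stripping
  f2 <- write_temp_fasta(c(">P1 some description", "kkdde*"))
  expect_equal(read_fasta(f2)$sequence, "KKDDE")

  # wrapped multi-record file round-trips byte-identically after
  # normalization
  recs3 <- tibble::tibble(
    id = c("A1", "B2"),
    sequence = c(strrep("KRDEA", 30), strrep("MGSTP", 10)))
  out <- tempfile(fileext = ".fasta")
  write_fasta(recs3, out)
  back <- read_fasta(out)
  expect_identical(back$id, recs3$id)
  expect_identical(back$sequence, recs3$sequence)
})

test_that("malformed FASTA inputs fail loudly", {
  f <- write_temp_fasta(c("KKDDE", ">P1", "AAA"))
  expect_error(read_fasta(f), "line 1")

  dup <- write_temp_fasta(c(">P1", "KK", ">P1", "DD"))
  expect_error(read_fasta(dup), "P1")

  badres <- write_temp_fasta(c(">P1", "KK1DE"))
  expect_error(read_fasta(badres), "alphabet")

  empty <- write_temp_fasta(character(0))
  expect_warning(recs <- read_fasta(empty), "empty")
  expect_equal(nrow(recs), 0L)
})

test_that("annotation tables are schema-checked and joined by accession", {
  f <- write_temp_table(c(
    "id,group,functional_class,family",
    "P1,Viruses,viral icosahedral capsid,Nodaviridae",
    "P2,Eukaryota,,"))
  ann <- read_annotation_table(f)
  expect_equal(ann$family[1], "Nodaviridae")
  expect_equal(ann$functional_class[2], "") # empty optional field kept

  # tab dialect auto-detected
  ft <- write_temp_table(c("id\tgroup\tfunctional_class\tfamily",
                           "P1\tViruses\tcapsid\tFamX"), ext = ".tsv")
  expect_equal(read_annotation_table(ft)$group, "Viruses")

  bad <- write_temp_table(c("accession,group,functional_class,family",
                            "P1,Viruses,,"))
  expect_error(read_annotation_table(bad), "id")

  recs <- tibble::tibble(id = c("P1", "P9"), sequence = c("KK", "DD"),
                         group = NA, functional_class = NA, family = NA)
  joined <- annotate_records(recs, ann)
  expect_equal(joined$group, c("Viruses", NA)) # unannotated record kept
})

test_that("capsid tables are validated row by row", {
  f <- write_temp_table(c(
    "virus,family,genome_type,t_number,components,genome_segments,host_class,motor_packaged",
    "HPV,Papillomaviridae,dsDNA,pseudo7,L1:360;L2:72,7900,eukaryotic,FALSE",
    "BMV,Bromoviridae,+ssRNA,3,CP:180,3000;2000,eukaryotic,FALSE"))
  tab <- read_capsid_table(f)
  expect_equal(tab$components[[1]]$protein, c("L1", "L2"))
  expect_equal(tab$components[[1]]$copies, c(360L, 72L))
  expect_equal(tab$genome_segments[[2]], c(3000L, 2000L))

  zero <- write_temp_table(c(
    "virus,family,genome_type,t_number,components,genome_segments,host_class,motor_packaged",
    "X,F,ssDNA,1,CP:0,100,eukaryotic,FALSE"))
  expect_error(read_capsid_table(zero), "row 1")

  badtype <- write_temp_table(c(
    "virus,family,genome_type,t_number,components,genome_segments,host_class,motor_packaged",
    "X,F,ssRNA-RT,1,CP:60,100,eukaryotic,FALSE"))
  expect_error(read_capsid_table(badtype), "genome_type")
})

test_that("accepted capsid rows always satisfy the entry invariants", {
  # fuzz: randomly corrupted rows are either rejected or parse to valid
  # entries
  set.seed(101)
  header <- paste("virus,family,genome_type,t_number,components",
                  "genome_segments,host_class,motor_packaged", sep = ",")
  fields <- function() {
    comp <- sample(c("CP:60", "CP:-3", "CP:0", "CP:abc", "A:60;B:12", ""),
                   1)
    seg <- sample(c("3000", "0", "-5", "1000;2000", "x", ""), 1)
    gt <- sample(c("ssDNA", "dsRNA", "junk"), 1)
    sprintf("V,F,%s,1,%s,%s,eukaryotic,FALSE", gt, comp, seg)
  }
  for (i in 1:60) {
    f <- write_temp_table(c(header, fields()))
    res <- tryCatch(read_capsid_table(f), error = function(e) NULL)
    if (!is.null(res)) {
      comp <- res$components[[1]]
      expect_gte(nrow(comp), 1L)
      expect_true(all(comp$copies >= 1L))
      expect_true(all(res$genome_segments[[1]] >= 1L))
      expect_true(res$genome_type %in% c("ssDNA", "dsDNA", "+ssRNA",
                                         "dsRNA"))
    }
  }
})

test_that("precomputed per-component charges are honoured when present", {
  f <- write_temp_table(c(
    "virus,family,genome_type,t_number,components,genome_segments,host_class,motor_packaged,q_max",
    "HPV,Papillomaviridae,dsDNA,pseudo7,L1:360;L2:72,7900,eukaryotic,FALSE,10;20"))
  tab <- read_capsid_table(f)
  expect_equal(tab$components[[1]]$q_max, c(10, 20))
  expect_equal(total_qmax(tab$components[[1]]), 360 * 10 + 72 * 20)
})
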