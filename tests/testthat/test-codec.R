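test_that("vocabulary collects characters, orders deterministically, appends sentinels", {
  v <- smiles_vocabulary(c("CO", "CN"))
  expect_s3_class(v, "smiles_vocabulary")
  expect_equal(v$tokens, c("C", "N", "O", "G", "E"))
  expect_length(v, 5)
  expect_equal(unname(v$index[v$tokens]), 1:5)

  expect_length(smiles_vocabulary("CC"), 3)
  expect_identical(smiles_vocabulary(c("CO", "CN")),
                   smiles_vocabulary(c("CN", "CO", "CO")))

  expect_error(smiles_vocabulary(character(0)), "non-empty")
  expect_error(smiles_vocabulary(c("CO", "")), "empty")
  expect_error(smiles_vocabulary("CGe"), "sentinel")
  expect_error(smiles_vocabulary("CEN"), "sentinel")
})

test_that("one-hot encoding frames with sentinels and is exact", {
  v <- smiles_vocabulary(c("C", "O", "N"))  # chemistry columns C,N,O
  for (ch in c("C", "O", "N")) {
    e <- encode_smiles(ch, v)
    expect_equal(dim(e$matrix), c(3, 5))
    expect_true(all(rowSums(e$matrix) == 1))
    # first row is the begin sentinel, last the end sentinel
    expect_equal(v$tokens[which(e$matrix[1, ] == 1)], "G")
    expect_equal(v$tokens[which(e$matrix[3, ] == 1)], "E")
    # the chemistry row is one-hot at the character's own column
    onehot <- e$matrix[2, 1:3]
    expected <- as.integer(c("C", "N", "O") == ch)
    expect_equal(unname(onehot), expected)
  }
  e <- encode_smiles("CON", v)
  expect_equal(nrow(e$matrix), nchar("CON") + 2)
  expect_identical(e$source, "CON")
  expect_error(encode_smiles("CXO", v), "'X' at position 2")
})

test_that("decoding strips sentinels and truncates at the first end sentinel", {
  v <- smiles_vocabulary(c("CO", "CN"))
  iG <- v$index[["G"]]; iE <- v$index[["E"]]; iC <- v$index[["C"]]
  expect_equal(decode_indices(c(iG, iC, iE), v), "C")
  expect_equal(decode_indices(c(iG, iC, iC, iE, iC), v), "CC")
  expect_error(decode_indices(c(iG, 99L), v), "out of range")
})

test_that("decode(encode(s)) round-trips every corpus string", {
  corpus <- toy_smiles_corpus(50, seed = 123)
  v <- smiles_vocabulary(corpus)
  for (s in corpus) {
    expect_identical(decode_indices(encode_smiles(s, v), v), s)
  }
})

test_that("smi files round-trip with identifiers and skip comments", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# header comment", "CCO\tmol1", "", "CCN\tmol2", "CCC"),
             path)
  smi <- read_smiles_file(path)
  expect_equal(unname(smi), c("CCO", "CCN", "CCC"))
  expect_equal(names(smi), c("mol1", "mol2", ""))

  out <- withr::local_tempfile(fileext = ".smi")
  write_smiles_file(smi, out)
  expect_equal(read_smiles_file(out), smi)
})

test_that("vocabulary JSON round-trips and validates sentinels", {
  v <- smiles_vocabulary(c("CCO", "c1ccccc1"))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, path)
  expect_identical(read_vocabulary(path), v)

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(tokens = c("C", "G")), bad)
  expect_error(read_vocabulary(bad), "sentinel")
})
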