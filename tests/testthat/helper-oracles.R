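## Independent oracles and fixture builders shared by the test files.
## The oracles deliberately use different algorithms from the package code
## they check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Longest common substring by diagonal sweep: every (start_a, start_b)
## offset pair lies on one diagonal, on which exact-match runs are found with
## rle().  Independent of the package's dynamic-programming core.
lcs_oracle <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(av)
  m <- length(bv)
  best <- 0L
  for (off in (-(m - 1L)):(n - 1L)) {
    ia <- max(1L, 1L + off):min(n, m + off)
    ib <- ia - off
    eq <- av[ia] == bv[ib] & av[ia] %in% BASES
    if (any(eq)) {
      r <- rle(eq)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  best
}

## Full Smith-Waterman (Gotoh) affine-gap local alignment score in plain R.
## A gap of length L costs gap_open + L * gap_ext.
sw_oracle <- function(a, b, match = 1, mismatch = -3,
                      gap_open = 1, gap_ext = 1) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(av)
  m <- length(bv)
  open_cost <- gap_open + gap_ext
  Hprev <- numeric(m + 1L)
  Eprev <- rep(-Inf, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1L)
    E <- rep(-Inf, m + 1L)   # E: gap in b (vertical), carried across rows
    Fj <- -Inf               # F: gap in a (horizontal), within-row
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] %in% BASES) match else mismatch
      E[j + 1L] <- max(Hprev[j + 1L] - open_cost, Eprev[j + 1L] - gap_ext)
      Fj <- max(H[j] - open_cost, Fj - gap_ext)
      H[j + 1L] <- max(0, Hprev[j] + s, E[j + 1L], Fj)
      if (H[j + 1L] > best) best <- H[j + 1L]
    }
    Hprev <- H
    Eprev <- E
  }
  best
}

## --- fixture builders -----------------------------------------------------

write_test_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}

write_test_bed <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(apply(df, 1L, function(r)
    paste(r[["chromosome"]], r[["start"]], r[["end"]], r[["element_id"]],
          0L, r[["strand"]], sep = "\t")), path)
  path
}

write_test_gff3 <- function(df, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             apply(df, 1L, function(r)
               paste(r[["chromosome"]], "test", "repeat_region",
                     r[["start1"]], r[["end1"]], ".", r[["strand"]], ".",
                     sprintf("ID=%s;family=%s", r[["element_id"]],
                             r[["family"]]),
                     sep = "\t")))
  writeLines(lines, path)
  path
}

## A tiny 3-element catalog on disk (FASTA + BED), returned with its paths.
tiny_catalog_files <- function(len = 40L, seed = 42L) {
  set.seed(seed)
  seqs <- list(elA = rand_seq(len), elB = rand_seq(len), elC = rand_seq(len))
  df <- data.frame(chromosome = c("chrI", "chrI", "chrII"),
                   start = c(100L, 500L, 30L),
                   end = c(100L + len, 500L + len, 30L + len),
                   element_id = c("elA", "elB", "elC"),
                   strand = c("+", "-", "+"),
                   stringsAsFactors = FALSE)
  list(fasta = write_test_fasta(seqs), bed = write_test_bed(df),
       seqs = seqs, df = df)
}

## Worked-example fixtures shipped with the package.
worked_example <- function() {
  counts <- read_clone_counts(system.file(
    "extdata", "worked_example_clone_counts.tsv", package = "tynahr"))
  plugs <- read_plug_surveys(system.file(
    "extdata", "worked_example_plugs.tsv", package = "tynahr"))
  list(induced = counts$MH3359$induced, uninduced = counts$MH3359$uninduced,
       survey = plugs$MH3359)
}

published_table <- function(strain) {
  read_outcome_table(system.file("extdata", "published_outcome_tables.tsv",
                                 package = "tynahr"), strain = strain)
}
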