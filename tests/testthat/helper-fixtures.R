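# Shared fixture builders; everything is generated in code at test time.

make_sheet <- function(groups, include = NULL) {
  n <- sum(groups)
  group <- rep(names(groups), groups)
  sheet <- data.frame(
    sample_id = paste0(group, "_", unlist(lapply(groups, seq_len))),
    group = group,
    lot = paste0(group, "_lot1"),
    replicate = unlist(lapply(groups, seq_len)),
    include = if (is.null(include)) rep(TRUE, n) else include,
    stringsAsFactors = FALSE)
  sheet
}

write_sheet <- function(sheet, path = tempfile(fileext = ".csv")) {
  write.csv(sheet, path, row.names = FALSE)
  path
}

# A tiny deterministic raw set built directly (no generator), n_spots x samples.
tiny_raw_files <- function(n_spots = 5, sample_ids = c("a", "b", "c"),
                           dir = tempfile()) {
  dir.create(dir)
  probe_id <- sprintf("P%03d", seq_len(n_spots))
  paths <- character(0)
  for (i in seq_along(sample_ids)) {
    tab <- data.frame(probe_id = probe_id,
                      fg_median = 100 + 10 * seq_len(n_spots) + i,
                      bg_median = 50 + seq_len(n_spots))
    p <- file.path(dir, paste0(sample_ids[i], ".tsv"))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  names(paths) <- sample_ids
  paths
}

# Small preprocessed synthetic dataset shared by several univariate /
# pipeline tests (built once per test run).
shared_small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        n_unique_probes = 600,
        group_sizes = c(media = 5, reference = 6, test = 6, nonequivalent = 5),
        n_responsive = 60, seed = 42)
      gen <- generate_dataset(cfg)
      expr <- preprocess(gen$raw, gen$sheet)
      cache <<- list(gen = gen, expr = expr)
    }
    cache
  }
})

# Independent brute-force mvt: direct double loops over pair means.
oracle_mvt <- function(d, g, h) {
  m_between <- mean(d[g, h])
  within <- function(s) {
    tot <- 0; cnt <- 0
    for (i in seq_along(s)) for (j in seq_along(s)) if (i < j) {
      tot <- tot + d[s[i], s[j]]; cnt <- cnt + 1
    }
    tot / cnt
  }
  m_between / (within(g) + within(h))
}
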