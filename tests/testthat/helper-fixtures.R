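# In-code fixture builders shared across test files.

tiny_counts <- function(values = rbind(c(3L, 0L), c(10L, 7L)),
                        genes = paste0("g", seq_len(nrow(values))),
                        samples = paste0("s", seq_len(ncol(values)))) {
  m <- values
  dimnames(m) <- list(genes, samples)
  count_matrix(m)
}

tiny_samples <- function(n_control = 2, n_cr = 2, tissue = "hypothalamus",
                         duration = "short") {
  n <- n_control + n_cr
  sample_table(data.frame(
    sample_id = paste0("s", seq_len(n)),
    treatment = rep(c("control", "CR"), c(n_control, n_cr)),
    tissue = tissue,
    duration = duration,
    stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# feature table built directly from a numeric matrix (samples x genes)
feature_table_from <- function(x, label, tissue = rep("t1", nrow(x))) {
  ft <- as.data.frame(x)
  ft$tissue <- factor(tissue)
  attr(ft, "label") <- factor(label, levels = c("control", "CR"))
  class(ft) <- c("cr_features", "data.frame")
  ft
}

# random small mixed table for the weighter property suite
random_small_table <- function(n = 8, bins = 3) {
  type <- sample(c("numeric", "categorical"), 1)
  f <- if (type == "numeric") round(stats::runif(n, 0, 10), 2)
       else sample(letters[1:3], n, replace = TRUE)
  y <- factor(sample(c("control", "CR"), n, replace = TRUE))
  while (nlevels(droplevels(y)) < 2)
    y <- factor(sample(c("control", "CR"), n, replace = TRUE))
  list(f = f, y = y, bins = bins)
}

# edge rows helper for relation fixtures
relation_rows <- function(subject, stype, object, otype,
                          relation = "regulation", sign = "positive",
                          sentences = 1) {
  do.call(rbind, lapply(seq_along(subject), function(i) {
    data.frame(subject = subject[i], subject_type = stype[i],
               object = object[i], object_type = otype[i],
               relation_type = relation, sign = sign,
               sentence = sprintf("sentence %d about %s-%s.",
                                  seq_len(sentences[min(i, length(sentences))]),
                                  subject[i], object[i]),
               stringsAsFactors = FALSE)
  }))
}
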