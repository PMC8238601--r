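# small typed-network builders used across tests

tn <- function(from, to, role = "target", relation = "ppi") {
  ids <- sort(unique(c(from, to)))
  typed_network(data.frame(id = ids, role = role, stringsAsFactors = FALSE),
                data.frame(from = from, to = to, relation = relation,
                           stringsAsFactors = FALSE))
}

path3 <- function() tn(c("a", "b"), c("b", "c"))

star_net <- function(n_leaves) {
  tn(rep("hub", n_leaves), sprintf("l%02d", seq_len(n_leaves)))
}

k3 <- function() tn(c("A", "A", "B"), c("B", "C", "C"))

record_df <- function(id, ob, mw, caco2, dl, include_listed = FALSE,
                      herbs = "ZM") {
  component_records(data.frame(
    id = id, name = paste0("name-", id), herbs = herbs,
    mw = mw, ob = ob, caco2 = caco2, dl = dl,
    include_listed = include_listed, stringsAsFactors = FALSE
  ))
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
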