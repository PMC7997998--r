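# Shared helper: read a TSV whose comment lines start with '#' but whose
# data fields may legitimately contain '#' (SMARTS atomic-number primitives
# such as [#7]), so read.delim's comment.char cannot be used.
fl_read_tsv_hash_safe <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    stringsAsFactors = FALSE)
}
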