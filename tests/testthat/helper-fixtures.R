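# small in-code fixtures shared across test files

two_stage <- function() {
  respsel::stage_sequence(c("Changhsingian", "Induan"), boundary = 1)
}

five_stage <- function() {
  respsel::stage_sequence(paste0("S", 1:5), boundary = 3)
}

# write a delimited fixture file and return its path
write_fixture <- function(lines, ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_occurrences <- function() {
  tibble::tibble(
    genus = c("Aa", "Bb", "Bb", "Cc", "Dd", "Dd", "Ee"),
    clade = c("brachiopod", "brachiopod", "brachiopod", "gastropod",
              "gastropod", "gastropod", "gastropod"),
    interval = c("Changhsingian", "Changhsingian", "Induan", "Induan",
                 "Changhsingian", "Induan", "Changhsingian"),
    locality = c("L1", "L1", "L2", "L3", "L1", "L2", "L2")
  )
}
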