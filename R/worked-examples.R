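#' Worked-example sentences with typed mentions
#'
#' A small set of annotated example sentences from the marine natural
#' products literature, shipped with the package. Each example carries the
#' raw sentence (with Markdown-style emphasis markers, as extracted) and its
#' typed entity mentions; character offsets are not stored but recomputed on
#' the normalized text with [normalize_text()] and [locate_span()], which is
#' also how the examples are used in the package's tests.
#'
#' @return A list of examples, each a list with `raw` (string) and
#'   `mentions` (data.frame `surface`, `etype`).
#' @examples
#' ex <- worked_examples()
#' s <- normalize_text(ex[[1]]$raw)
#' locate_span(s, "Culcita") # c(90, 96)
#' @export
worked_examples <- function() {
  path <- system.file("extdata", "worked_examples.json", package = "mnpner",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw$examples, function(ex) {
    list(raw = ex$raw,
         mentions = do.call(rbind, lapply(ex$mentions, function(m) {
           data.frame(surface = m$surface, etype = m$etype,
                      stringsAsFactors = FALSE)
         })))
  })
}
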