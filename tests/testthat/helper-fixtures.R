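# A small demonstration target: 14 qualitative states over two coupled
# enzymatic conversions (variables A, AP, B, BP), used as a hand-checkable
# target-state fixture for the fitness algebra.
demo_target_states <- function() {
  rows <- c(
    "zer,pos", "pos,neg", "pos,neg", "pos,neg",
    "pos,pos", "pos,pos", "zer,pos", "pos,neg",
    "pos,zer", "pos,zer", "pos,neg", "pos,neg",
    "pos,pos", "pos,pos", "pos,neg", "pos,neg",
    "pos,neg", "zer,pos", "pos,neg", "pos,neg",
    "zer,pos", "pos,neg", "pos,zer", "pos,neg",
    "pos,zer", "pos,neg", "pos,zer", "pos,neg",
    "pos,neg", "pos,zer", "pos,zer", "pos,neg",
    "pos,zer", "pos,zer", "pos,zer", "pos,neg",
    "pos,neg", "pos,pos", "pos,zer", "pos,neg",
    "zer,zer", "zer,zer", "zer,zer", "zer,zer",
    "pos,pos", "pos,zer", "zer,zer", "zer,zer",
    "pos,pos", "pos,zer", "pos,zer", "pos,zer",
    "pos,pos", "pos,neg", "pos,pos", "pos,zer")
  df <- as.data.frame(matrix(rows, ncol = 4L, byrow = TRUE),
                      stringsAsFactors = FALSE)
  colnames(df) <- c("A", "AP", "B", "BP")
  states_from_table(df)
}
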