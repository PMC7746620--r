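# internal helpers

# rbind a list of data.frames, ignoring NULLs; returns NULL when nothing
# remains (base rbind mis-dispatches when every element is NULL)
rbind_df <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  lst <- Filter(function(d) nrow(d) > 0L, lst)
  if (length(lst) == 0L) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}
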