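# Strip class and run attributes from a trajectory for column-wise comparison.
traj_cols <- function(x) as.list(x)[names(x)]
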