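# Bitwise reproducibility across the compiled and pure-R engines requires
# strict per-operation IEEE semantics (no fused multiply-add contraction).
PKG_CXXFLAGS = -ffp-contract=off
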