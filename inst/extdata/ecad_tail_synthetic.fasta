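>ecad_tail_synthetic | synthetic stand-in for the E-cadherin cytoplasmic tail: 148 aa, net charge -22; segment net charges A(1-70) = -13, B(71-124) = -5, C(125-148) = -4; A-segment has a positive N-terminal block followed by a negative stretch
RVSVKLKKKNRASQVLQKTGPKRKPGLDVEDSLENLEQEDNSEEVQVESTDDQAEDPEEDGQDTEETEDEKELPVTSSEVTDTNSLPLQSNLTEEDVLEEKQDGTDRKTGENEVKSRTPKNVAPDEESKPPEADEARNGLASQSKEVA
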