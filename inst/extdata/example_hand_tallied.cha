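@Begin
@Participants:	PAR Participant
*PAR:	the boy &-uh looked (1.2) into the jar .
*PAR:	<the> [/] the frog was gone you know .
*PAR:	he went [//] walked t:o the window (0.8) quickly .
*PAR:	then the the dog um fell (2.0) down .
@End
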