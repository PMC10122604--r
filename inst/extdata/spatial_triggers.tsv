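# Mini spatial-trigger term list: prepositions and trigger verbs that evoke
# a spatial relation between a finding/device and an anatomical location.
of
in
within
at
near
above
below
beneath
along
adjacent to
overlying
abutting
demonstrate
demonstrates
show
shows
reveal
reveals
are
terminates
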