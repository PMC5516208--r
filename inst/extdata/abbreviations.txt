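# words whose trailing period does not end a sentence (matched case-insensitively)
dr
mr
mrs
ms
st
vs
etc
jr
sr
prof
rev
no
fig
approx
dept
inc
ltd
co
e.g
i.e
a.m
p.m
u.s
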