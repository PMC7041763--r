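stack	dg37
AA/UU	-0.93
AU/UA	-1.10
AC/UG	-2.24
AG/UC	-2.08
AG/UU	-0.50
AU/UG	-0.50
UA/AU	-1.33
UU/AA	-0.93
UC/AG	-2.35
UG/AC	-2.11
UG/AU	-0.50
UU/AG	-0.50
CA/GU	-2.11
CU/GA	-2.08
CC/GG	-3.26
CG/GC	-2.36
CG/GU	-0.50
CU/GG	-0.50
GA/CU	-2.35
GU/CA	-2.24
GC/CG	-3.42
GG/CC	-3.26
GG/CU	-0.50
GU/CG	-0.50
GA/UU	-0.50
GU/UA	-0.50
GC/UG	-0.50
GG/UC	-0.50
GG/UU	-0.50
GU/UG	-0.50
UA/GU	-0.50
UU/GA	-0.50
UC/GG	-0.50
UG/GC	-0.50
UG/GU	-0.50
UU/GG	-0.50
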