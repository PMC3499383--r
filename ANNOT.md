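# Annotated prohormone sequence format

Plain-text dialect for protein sequences with cleavage-site annotations,
read by `read_annotated()` and written by `write_annotated()`.

## Grammar

```
file        := record*
record      := header newline body
header      := ">" id [ " [signal=" INT "]" ]
body        := (seqline newline annotline newline)+
seqline     := [A-Z]+            ; residues: 20 standard AAs plus X
annotline   := [.|]+             ; same length as the seqline above it
```

* `id` — record identifier, no whitespace.
* `[signal=N]` — optional N-terminal signal-peptide length in residues.
* Sequence is wrapped at 60 residues per line; each sequence line is
  followed by its annotation line, character-aligned beneath it.
* `|` marks a cleaved position, written under the P1 residue: cleavage
  occurs C-terminal to that residue. `.` marks every other position.
* The total sequence and annotation track lengths must be equal.
* A `|` under a residue other than K or R is a validation error
  (a warning in lenient mode).
* Lowercase residues are accepted on input and uppercased.

Because sequence lines (`A-Z`) and annotation lines (`.|`) use disjoint
character sets, readers also accept the two tracks as separate blocks;
the writer always emits aligned pairs. All positions in reports derived
from this format are 1-based.

## Example

```
>toy1 [signal=2]
MAKRSA
...|..
```

One record, six residues, signal length 2, a single cleavage C-terminal
to the arginine at position 4.
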