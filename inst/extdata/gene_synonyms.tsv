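# Editable gene-symbol synonym table: free-text or locus symbols mapped to
# canonical tokens before family-token extraction.
symbol	canonical
LOC101107624	BSP5C
BSP5L	BSP5C
LOC101105521	BSP3
SEMINAL PLASMA PROTEIN BSP-30 KDA LIKE	BSPH2
BSP-30 KDA LIKE	BSPH2
SEMINAL PLASMA PROTEIN A3-LIKE	BSP3
SPA3	BSP3
SP1	BSP1
RSVP14	BSP1
RSVP20	BSP5
RSVP22	BSP5C
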