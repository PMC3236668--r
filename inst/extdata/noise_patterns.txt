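# Default noise patterns, one per line: <group><TAB><regex>
# Groups: quoted_reply, attribution, forwarded_block, signature_delim,
#   signature_line, advertisement, virus_notice, client_notice, image_ref
# quoted_reply / attribution / advertisement / virus_notice / client_notice /
#   image_ref patterns remove single matching lines; forwarded_block patterns
#   remove everything from the matching line to the end of the message;
#   signature_delim likewise; signature_line feeds the trailing-lines
#   signature heuristic.
quoted_reply	^\s*[>|]
attribution	^On\b.{0,200}\bwrote:\s*$
attribution	^.{0,100}\bwrote:\s*$
forwarded_block	^-{3,}\s*Original Message\s*-{3,}
forwarded_block	^Begin forwarded message
forwarded_block	^-{3,}\s*Forwarded message\s*-{3,}
signature_delim	^--\s*$
signature_line	\b(?:DDS|DMD|MS|PhD|FAGD|MAGD)\b
signature_line	\bwww\.[A-Za-z0-9.-]+
signature_line	https?://
signature_line	\b\d{3}[-. ]\d{3}[-. ]\d{4}\b
signature_line	^(?:Dr|Drs)\.\s
advertisement	(?i)\bunsubscribe\b
advertisement	(?i)visit our (?:website|sponsor)
advertisement	(?i)special offer|limited time only
advertisement	^_{5,}\s*$
advertisement	^={5,}\s*$
virus_notice	(?i)no virus found in this (?:incoming|outgoing) message
virus_notice	(?i)checked by (?:AVG|avast|norton)
virus_notice	(?i)certified (?:virus|spam)[- ]free
virus_notice	(?i)scanned (?:by|for viruses)
client_notice	(?i)sent (?:from|via) (?:my )?(?:Microsoft Outlook|Outlook|iPhone|BlackBerry)
client_notice	(?i)Microsoft Outlook.*notice
image_ref	^\s*\[(?:image|cid|attachment)[^\]]*\]\s*$
image_ref	^\s*<<[^>]*\.(?:jpe?g|png|gif|bmp|tiff?)>>\s*$
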