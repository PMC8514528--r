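instruments:
- name: hsps
  trait: sps
  scale:
  - 1.0
  - 7.0
  scoring: sum
  alt_scoring: none
  items:
  - id: hsps_q2
    reverse: no
    subdomain: aes
  - id: hsps_q3
    reverse: no
    subdomain: eoe
  - id: hsps_q4
    reverse: no
    subdomain: eoe
  - id: hsps_q5
    reverse: no
    subdomain: lst
  - id: hsps_q6
    reverse: no
    subdomain: eoe
  - id: hsps_q7
    reverse: no
    subdomain: lst
  - id: hsps_q8
    reverse: no
    subdomain: aes
  - id: hsps_q9
    reverse: no
    subdomain: lst
  - id: hsps_q10
    reverse: no
    subdomain: aes
  - id: hsps_q12
    reverse: no
    subdomain: aes
  - id: hsps_q13
    reverse: no
    subdomain: eoe
  - id: hsps_q14
    reverse: no
    subdomain: eoe
  - id: hsps_q15
    reverse: no
    subdomain: aes
  - id: hsps_q16
    reverse: no
    subdomain: eoe
  - id: hsps_q17
    reverse: no
    subdomain: eoe
  - id: hsps_q18
    reverse: no
    subdomain: lst
  - id: hsps_q19
    reverse: no
    subdomain: lst
  - id: hsps_q20
    reverse: no
    subdomain: eoe
  - id: hsps_q21
    reverse: no
    subdomain: eoe
  - id: hsps_q22
    reverse: no
    subdomain: aes
  - id: hsps_q23
    reverse: no
    subdomain: eoe
  - id: hsps_q24
    reverse: no
    subdomain: eoe
  - id: hsps_q25
    reverse: no
    subdomain: eoe
  - id: hsps_q26
    reverse: no
    subdomain: lst
  - id: hsps_q27
    reverse: no
    subdomain: aes
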