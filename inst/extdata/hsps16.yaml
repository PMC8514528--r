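instruments:
- name: hsps
  trait: sps
  scale:
  - 1.0
  - 7.0
  scoring: sum
  alt_scoring: none
  items:
  - id: hsps_q1
    reverse: no
  - id: hsps_q3
    reverse: no
    subdomain: eoe
  - id: hsps_q4
    reverse: no
    subdomain: eoe
  - id: hsps_q6
    reverse: no
    subdomain: eoe
  - id: hsps_q7
    reverse: no
    subdomain: lst
  - id: hsps_q9
    reverse: no
    subdomain: lst
  - id: hsps_q13
    reverse: no
    subdomain: eoe
  - id: hsps_q14
    reverse: no
    subdomain: eoe
  - id: hsps_q16
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
  - id: hsps_q23
    reverse: no
    subdomain: eoe
  - id: hsps_q24
    reverse: no
    subdomain: eoe
  - id: hsps_q25
    reverse: no
    subdomain: eoe
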