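<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for the versioned-release XML dialect: one dated knowledgebase
     snapshot per file. Annotation removal between releases is encoded as
     absence in the later file; there is no tombstone element. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:simpleType name="categoryType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="catalytic-activity"/>
      <xs:enumeration value="function-info"/>
      <xs:enumeration value="go-biological-process"/>
      <xs:enumeration value="go-molecular-function"/>
      <xs:enumeration value="pathway"/>
      <xs:enumeration value="transport-activity"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="evidenceKindType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="direct-assay"/>
      <xs:enumeration value="physical-interaction"/>
      <xs:enumeration value="sequence-similarity"/>
      <xs:enumeration value="curator-inference"/>
      <xs:enumeration value="author-statement"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="existenceType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="PE1"/>
      <xs:enumeration value="PE2"/>
      <xs:enumeration value="PE3"/>
      <xs:enumeration value="PE4"/>
      <xs:enumeration value="PE5"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="granularityType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="day"/>
      <xs:enumeration value="year"/>
    </xs:restriction>
  </xs:simpleType>

  <!-- full date (YYYY-MM-DD) or, with granularity="year", a bare year -->
  <xs:simpleType name="pubDateType">
    <xs:restriction base="xs:string">
      <xs:pattern value="[0-9]{4}(-[0-9]{2}-[0-9]{2})?"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="release">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="entry" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="annotation" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="evidence" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="publication" minOccurs="0" maxOccurs="1">
                            <xs:complexType>
                              <xs:attribute name="id" type="xs:string" use="required"/>
                              <xs:attribute name="date" type="pubDateType" use="required"/>
                              <xs:attribute name="granularity" type="granularityType" use="required"/>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                        <xs:attribute name="kind" type="evidenceKindType" use="required"/>
                        <xs:attribute name="negative" type="xs:boolean" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="category" type="categoryType" use="required"/>
                  <xs:attribute name="term" type="xs:string" use="optional"/>
                  <xs:attribute name="label" type="xs:string" use="optional"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="accession" type="xs:string" use="required"/>
            <xs:attribute name="chromosome" type="xs:string" use="required"/>
            <xs:attribute name="existence" type="existenceType" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="id" type="xs:string" use="required"/>
      <xs:attribute name="date" type="xs:date" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
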